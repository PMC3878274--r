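#' Majority-rule consensus with averaged branch lengths
#'
#' Builds the rooted majority-rule consensus of a set of trees over one tip
#' set: a clade is kept iff its frequency across the input trees is strictly
#' greater than `threshold` (so exact ties at 50% are dropped), and each kept
#' edge receives the arithmetic mean of the corresponding subtending branch
#' length over the trees that contain that clade. Terminal branches are
#' present in every tree and are averaged over all of them. The output is
#' generally non-binary.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) over an identical tip
#'   label set; all trees are treated as rooted.
#' @param threshold Clade-frequency cutoff in `(0.5, 1]`; kept iff
#'   frequency > threshold when `threshold = 0.5` (the default majority
#'   rule), iff frequency >= threshold otherwise.
#' @return A `phylo` consensus tree with branch lengths.
#' @export
consensus_tree <- function(trees, threshold = 0.5) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("empty tree set", call. = FALSE)
  stopifnot(threshold >= 0.5, threshold <= 1)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    labs <- sort(trees[[i]]$tip.label)
    if (!identical(labs, ref)) {
      off <- c(setdiff(labs, ref), setdiff(ref, labs))
      stop("tree ", i, " has a mismatched tip set; offending labels: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
  }
  n_trees <- length(trees)
  n_tip <- length(ref)

  counts <- new.env(hash = TRUE, parent = emptyenv())
  sums <- new.env(hash = TRUE, parent = emptyenv())
  sets <- new.env(hash = TRUE, parent = emptyenv())
  for (tr in trees) {
    validate_phylogeny(tr)
    ntip <- ape::Ntip(tr)
    idx <- match(tr$tip.label, ref)
    below <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) below[[i]] <- idx[i]
    po <- ape::reorder.phylo(tr, "postorder")
    for (i in seq_len(nrow(po$edge))) {
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      below[[p]] <- c(below[[p]], below[[ch]])
    }
    # edge above each non-root node defines a clade
    for (i in seq_len(nrow(tr$edge))) {
      ch <- tr$edge[i, 2L]
      key <- paste(sort(below[[ch]]), collapse = " ")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      sums[[key]] <- (sums[[key]] %||% 0) + tr$edge.length[i]
      if (is.null(sets[[key]])) sets[[key]] <- sort(below[[ch]])
    }
  }

  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]] / n_trees, numeric(1))
  keep <- if (threshold == 0.5) freq > 0.5 else freq >= threshold
  sizes <- vapply(keys, function(k) length(sets[[k]]), integer(1))
  keep <- keep | sizes == 1L  # tips always survive
  keys <- keys[keep]
  clade_sets <- lapply(keys, function(k) sets[[k]])
  clade_len <- vapply(keys, function(k) sums[[k]] / counts[[k]], numeric(1))

  # root clade (all tips), never an edge in the inputs
  root_key <- paste(seq_len(n_tip), collapse = " ")
  if (!(root_key %in% keys)) {
    keys <- c(keys, root_key)
    clade_sets <- c(clade_sets, list(seq_len(n_tip)))
    clade_len <- c(clade_len, 0)
  }

  # nest: parent of a clade = the smallest kept clade strictly containing it
  sz <- lengths(clade_sets)
  ord <- order(sz)  # children get resolved before larger clades
  parent_of <- rep(NA_integer_, length(keys))
  for (ii in seq_along(ord)) {
    i <- ord[ii]
    if (sz[i] == n_tip) next
    best <- NA_integer_; best_sz <- Inf
    for (j in seq_along(keys)) {
      if (sz[j] > sz[i] && sz[j] < best_sz && all(clade_sets[[i]] %in% clade_sets[[j]])) {
        best <- j; best_sz <- sz[j]
      }
    }
    parent_of[i] <- best
  }

  children_of <- split(seq_along(keys)[!is.na(parent_of)], parent_of[!is.na(parent_of)])
  root_i <- which(sz == n_tip)
  emit <- function(i) {
    kids <- children_of[[as.character(i)]]
    if (is.null(kids)) {
      lab <- ref[clade_sets[[i]]]
    } else {
      lab <- paste0("(", paste(vapply(kids, emit, character(1)), collapse = ","), ")")
    }
    if (i == root_i) paste0(lab, ";") else paste0(lab, ":", format(clade_len[i], digits = 12))
  }
  parse_newick(emit(root_i))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
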