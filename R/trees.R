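#' Parse a Newick string into a validated phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' downstream comparative machinery relies on: a single rooted tree, unique
#' non-empty tip labels, and finite non-negative branch lengths. Edges with
#' no length annotation are set to 0 with a warning rather than left `NULL`,
#' so every returned tree carries an `edge.length` vector.
#'
#' @param text Newick string (must end in `;`).
#' @return An object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w), call. = FALSE)
  )
  if (is.null(tr)) stop("Newick parse error: input is not a well-formed tree string", call. = FALSE)
  if (inherits(tr, "multiPhylo")) stop("expected a single tree, got ", length(tr), call. = FALSE)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; setting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("tree has edges without lengths; setting them to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  validate_phylogeny(tr)
  tr
}

#' Serialize a phylogeny to Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths (default 10).
#' @return A Newick string, always with branch lengths (zero lengths are
#'   written as `:0`, not omitted).
#' @export
write_newick <- function(tree, digits = 10) {
  validate_phylogeny(tree)
  ape::write.tree(tree, digits = digits)
}

#' Read trees from a Newick or Nexus file
#'
#' Nexus TREES blocks (including translate tables) are handled by
#' [ape::read.nexus()]; anything else is treated as plain Newick, one tree
#' per line.
#'
#' @param path File path.
#' @return A `multiPhylo` list of trees (possibly of length 1).
#' @export
read_trees <- function(path) {
  stopifnot(file.exists(path))
  head <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
  trees <- if (startsWith(head, "#NEXUS")) ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(trees)) stop("no trees could be read from ", path, call. = FALSE)
  if (inherits(trees, "phylo")) trees <- c(trees)
  class(trees) <- "multiPhylo"
  for (i in seq_along(trees)) validate_phylogeny(trees[[i]])
  trees
}

# Invariant checks shared by every entry point that accepts a tree.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stop("empty tip labels are not allowed", call. = FALSE)
  if (anyDuplicated(labs)) {
    stop("duplicate tip labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$edge.length)) {
    if (any(!is.finite(tree$edge.length))) stop("non-finite branch lengths", call. = FALSE)
    if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  }
  invisible(tree)
}

#' Node depths (distance from the root)
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Named numeric vector over all nodes (tips first, in
#'   `tree$tip.label` order, then internal nodes by number); the root has
#'   depth 0 and every child's depth is its parent's plus the connecting
#'   branch length.
#' @export
node_depths <- function(tree) {
  validate_phylogeny(tree)
  d <- ape::node.depth.edgelength(tree)
  names(d) <- c(tree$tip.label, as.character(ape::Ntip(tree) + seq_len(tree$Nnode)))
  d
}

#' Is the tree ultrametric?
#'
#' @param tree A `phylo` object.
#' @param tol Absolute tolerance on the spread of tip depths.
#' @return Logical flag.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  diff(range(d)) <= tol
}

#' Relative node times on an ultrametric tree
#'
#' Scales node depths by the root-to-tip depth so the root sits at 0 and the
#' present (every tip) at 1 — the time axis used by the DTT curve and the
#' time-dependent rate models.
#'
#' @param tree An ultrametric `phylo` object.
#' @param tol Ultrametricity tolerance.
#' @return Named vector of times in `[0, 1]` over all nodes.
#' @export
relative_times <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  if (diff(range(d[seq_len(ntip)])) > tol) {
    stop("tree is not ultrametric; date it first (see date_tree_pl)", call. = FALSE)
  }
  total <- max(d)
  if (total <= 0) stop("tree has zero depth", call. = FALSE)
  t <- d / total
  t[seq_len(ntip)] <- 1  # clamp tips exactly
  t
}

# Children of each node as a list indexed by node number; root id attached.
.tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  kids
}

# Postorder vector of internal node ids (children before parents).
.postorder_internal <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  unique(po$edge[, 1L])
}
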