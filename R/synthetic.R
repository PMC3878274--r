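#' Simulate a pure-birth (Yule) time tree
#'
#' Seeded wrapper around [phytools::pbtree()] producing an ultrametric
#' binary tree with exactly `n_tips` tips, rescaled so the root-to-tip
#' depth is exactly 1 (downstream node times are then already relative).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth Speciation rate (only affects the age distribution before
#'   rescaling).
#' @param seed Integer seed (mandatory: every generator here is
#'   reproducible by construction).
#' @return Ultrametric `phylo` of depth 1.
#' @export
simulate_yule <- function(n_tips, birth = 1, seed) {
  if (n_tips < 2) stop("need at least 2 tips", call. = FALSE)
  stopifnot(birth > 0, !missing(seed))
  set.seed(seed)
  tr <- phytools::pbtree(n = n_tips, b = birth, scale = 1, quiet = TRUE)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  tr
}

#' Simulate discrete states under a (possibly time-dependent) ER model
#'
#' Forward simulation of the 4-state equal-rates chain down the tree: the
#' root state is uniform over `1..k`, and each branch applies the ER
#' closed-form transition probabilities on the branch lengths produced by
#' [transform_branches()], so the simulator is the exact forward model of
#' the [mk_loglik()] likelihood for every model kind.
#'
#' @param tree Ultrametric `phylo`.
#' @param spec A `model_spec` (its `q` is the simulating rate).
#' @param seed Integer seed.
#' @param k Number of states.
#' @return A `coded_states` object over the tree's tips.
#' @export
simulate_mk <- function(tree, spec, seed, k = 4L) {
  stopifnot(inherits(spec, "model_spec"), !missing(seed))
  set.seed(seed)
  tr <- transform_branches(tree, spec)
  ntip <- ape::Ntip(tr)
  n_nodes <- ntip + tr$Nnode
  state <- integer(n_nodes)
  state[ntip + 1L] <- sample.int(k, 1L)
  po <- ape::reorder.phylo(tr, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {       # preorder traversal
    pa <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    e <- exp(-k * spec$q * po$edge.length[i])
    p <- rep((1 - e) / k, k)
    p[state[pa]] <- p[state[pa]] + e
    state[ch] <- sample.int(k, 1L, prob = p)
  }
  states <- state[seq_len(ntip)]
  names(states) <- tr$tip.label
  structure(list(states = states,
                 exclusions = data.frame(species = character(0), reason = character(0),
                                         stringsAsFactors = FALSE)),
            class = "coded_states")
}

#' Simulate Brownian motion on a tree
#'
#' Root value 0; each branch adds an independent Normal(0, rate * length)
#' increment.
#'
#' @param tree `phylo` with branch lengths.
#' @param bm_rate Rate (variance per unit branch length), > 0.
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm <- function(tree, bm_rate, seed) {
  if (bm_rate <= 0) stop("bm_rate must be > 0", call. = FALSE)
  stopifnot(!missing(seed))
  set.seed(seed)
  x <- .bm_tips(tree, bm_rate)
  names(x) <- tree$tip.label
  x
}

# BM tip values under the current RNG state (shared by dtt_null).
.bm_tips <- function(tree, bm_rate) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  val <- numeric(n_nodes)
  po <- ape::reorder.phylo(tree, "postorder")
  inc <- stats::rnorm(nrow(po$edge), 0, sqrt(bm_rate * po$edge.length))
  for (i in rev(seq_len(nrow(po$edge)))) {
    val[po$edge[i, 2L]] <- val[po$edge[i, 1L]] + inc[i]
  }
  val[seq_len(ntip)]
}

#' Generate the synthetic study fixture: risk table + dated tree
#'
#' Emulates the shape of the study data set without implying any real
#' phylogenetic placement: 48 pseudo-species named `Genus_sp01` ...
#' `Genus_sp48` with the IUCN category composition of the real table
#' (EN 1, VU 14, NT 9, LC 24), assigned to species in seeded random order,
#' plus a seeded unit-depth Yule tree over the same names.
#'
#' @param seed Integer seed.
#' @param dir Directory to write `risk_table.tsv` and `dated_tree.nwk`
#'   into (default: a fresh temp dir); `NULL` skips writing.
#' @return List with `table` (data.frame), `tree` (`phylo`), and the file
#'   paths (`NA` if not written).
#' @export
make_fixture_dataset <- function(seed, dir = tempfile("fixture")) {
  stopifnot(!missing(seed))
  n <- 48L
  species <- sprintf("Genus_sp%02d", seq_len(n))
  composition <- c(rep("EN", 1L), rep("VU", 14L), rep("NT", 9L), rep("LC", 24L))
  set.seed(seed)
  tab <- data.frame(order = "Ordo", family = "Familia", species = species,
                    common_name = paste("Synthetic species", seq_len(n)),
                    iucn = sample(composition), stringsAsFactors = FALSE)
  tree <- simulate_yule(n, seed = seed + 1L)
  tree$tip.label <- species
  table_path <- tree_path <- NA_character_
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    table_path <- file.path(dir, "risk_table.tsv")
    tree_path <- file.path(dir, "dated_tree.nwk")
    utils::write.table(tab, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(write_newick(tree), tree_path)
  }
  list(table = tab, tree = tree, table_path = table_path, tree_path = tree_path)
}

#' Path to the packaged verbatim species/IUCN table
#'
#' The real 48-species endemic-bird table (order, family, species, common
#' name, IUCN category) ships with the package for ingestion tests and the
#' worked example.
#'
#' @return File path inside the installed package.
#' @export
risk_table_fixture <- function() {
  system.file("extdata", "endemic_birds_iucn.tsv", package = "riskevo", mustWork = TRUE)
}
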