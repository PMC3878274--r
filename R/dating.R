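#' Penalized-likelihood ultrametricization
#'
#' Converts a rooted tree with (additive) branch lengths into an ultrametric
#' time tree by jointly estimating node ages and per-branch rates. The
#' objective is a Gaussian penalized fit
#' \deqn{\sum_e (b_e - r_e t_e)^2 + \lambda \sum_{(e,f)\ adjacent} (r_e - r_f)^2,}
#' where \eqn{b_e} is the observed branch length, \eqn{t_e = a_{child} -
#' a_{parent}} the implied duration, and adjacency means a parent edge and
#' one of its child edges. For fixed ages the rates minimize a quadratic
#' form and are profiled out exactly (a sparse linear solve); the outer
#' optimization runs over internal node ages, parameterized as fractions of
#' the open interval between each parent's age and the present so the
#' parent-older-than-child constraint holds by construction. Tips sit at
#' exactly `root_age`, so the output is ultrametric by construction.
#'
#' @param tree Rooted `phylo` with non-negative branch lengths.
#' @param smoothing Penalty weight \eqn{\lambda > 0} on rate changes between
#'   adjacent branches (dimensionless; default 1).
#' @param root_age Depth assigned to the root-to-tip span (default 1, so
#'   downstream node times are already relative).
#' @param tol Convergence tolerance passed to the optimizer.
#' @param max_iter Iteration cap for the outer optimization.
#' @return An ultrametric `phylo`; the fitted per-branch rates are attached
#'   as `attr(tree, "rates")` and the objective value as
#'   `attr(tree, "objective")`.
#' @export
date_tree_pl <- function(tree, smoothing = 1, root_age = 1, tol = 1e-9,
                         max_iter = 1000L) {
  validate_phylogeny(tree)
  stopifnot(smoothing > 0, root_age > 0)
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  n_nodes <- ntip + tree$Nnode
  edge <- tree$edge
  b <- tree$edge.length
  parent_edge_of <- integer(n_nodes)          # edge index above each node, 0 at root
  parent_edge_of[edge[, 2L]] <- seq_len(nrow(edge))
  free <- setdiff((ntip + 1L):n_nodes, root)  # internal non-root nodes
  preord <- .preorder_nodes(tree)

  # adjacency pairs (parent edge, child edge)
  pair_p <- integer(0); pair_c <- integer(0)
  for (i in seq_len(nrow(edge))) {
    pe <- parent_edge_of[edge[i, 1L]]
    if (pe > 0L) { pair_p <- c(pair_p, pe); pair_c <- c(pair_c, i) }
  }

  ages_from_frac <- function(f) {
    a <- numeric(n_nodes)
    a[seq_len(ntip)] <- root_age
    a[root] <- 0
    for (v in preord) {
      if (v == root || v <= ntip) next
      p <- edge[parent_edge_of[v], 1L]
      a[v] <- a[p] + f[v] * (root_age - a[p])
    }
    a
  }

  profile_rates <- function(tt) {
    ne <- length(tt)
    A <- diag(tt^2 + 1e-12, ne)
    for (j in seq_along(pair_p)) {
      p <- pair_p[j]; ch <- pair_c[j]
      A[p, p] <- A[p, p] + smoothing
      A[ch, ch] <- A[ch, ch] + smoothing
      A[p, ch] <- A[p, ch] - smoothing
      A[ch, p] <- A[ch, p] - smoothing
    }
    solve(A, b * tt)
  }

  objective_from_ages <- function(a) {
    tt <- a[edge[, 2L]] - a[edge[, 1L]]
    r <- profile_rates(tt)
    sum((b - r * tt)^2) + smoothing * sum((r[pair_p] - r[pair_c])^2)
  }

  obj <- function(theta) {
    f <- numeric(n_nodes)
    f[free] <- stats::plogis(theta)
    objective_from_ages(ages_from_frac(f))
  }

  # init ages from the path-proportional heuristic a_v = d_v / (d_v + h_v),
  # d = depth from root, h = mean remaining distance to descendant tips
  d <- ape::node.depth.edgelength(tree)
  h <- numeric(n_nodes)
  po_edges <- ape::reorder.phylo(tree, "postorder")$edge
  po_len <- ape::reorder.phylo(tree, "postorder")$edge.length
  acc <- vector("list", n_nodes)
  for (i in seq_len(nrow(po_edges))) {
    p <- po_edges[i, 1L]; ch <- po_edges[i, 2L]
    contrib <- if (ch <= ntip) po_len[i] else po_len[i] + h[ch]
    acc[[p]] <- c(acc[[p]], contrib)
    h[p] <- mean(acc[[p]])
  }
  a0 <- numeric(n_nodes)
  a0[seq_len(ntip)] <- root_age
  denom <- d + h
  a0[free] <- ifelse(denom[free] > 0, root_age * d[free] / denom[free], root_age * 0.5)
  f0 <- numeric(n_nodes)
  for (v in preord) {
    if (v == root || v <= ntip) next
    p <- edge[parent_edge_of[v], 1L]
    fr <- (a0[v] - a0[p]) / (root_age - a0[p])
    f0[v] <- min(max(fr, 0.02), 0.98)
    a0[v] <- a0[p] + f0[v] * (root_age - a0[p])
  }

  res <- stats::nlminb(stats::qlogis(f0[free]), obj,
                       control = list(iter.max = max_iter, eval.max = 10L * max_iter,
                                      rel.tol = tol))
  converged <- res$convergence == 0 ||
    grepl("converg", res$message, ignore.case = TRUE)
  if (!converged || !is.finite(res$objective)) {
    stop("penalized-likelihood dating did not converge: ", res$message,
         " (objective = ", format(res$objective), ", iterations = ",
         res$iterations, ")", call. = FALSE)
  }
  f <- numeric(n_nodes)
  f[free] <- stats::plogis(res$par)
  a <- ages_from_frac(f)
  tt <- a[edge[, 2L]] - a[edge[, 1L]]
  out <- tree
  out$edge.length <- tt
  attr(out, "rates") <- profile_rates(tt)
  attr(out, "objective") <- res$objective
  out
}

# Preorder (root first) vector of node ids.
.preorder_nodes <- function(tree) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  c(ape::Ntip(tree) + 1L, rev(edge[, 2L]))
}
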