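#' Equal-rates transition probability matrix
#'
#' Closed form for the k-state equal-rates (ER) Markov chain with all
#' off-diagonal generator entries equal to `q`:
#' \deqn{P_{ii}(t) = 1/k + (1 - 1/k) e^{-kqt}, \quad
#'       P_{ij}(t) = (1 - e^{-kqt})/k.}
#' Rows sum to 1 and the chain relaxes to the uniform stationary
#' distribution as `q t` grows.
#'
#' @param q Transition rate (events per unit time), >= 0.
#' @param t Elapsed time, >= 0.
#' @param k Number of states (default 4).
#' @return A `k` x `k` stochastic matrix.
#' @export
transition_matrix_er <- function(q, t, k = 4L) {
  if (q < 0) stop("negative rate q", call. = FALSE)
  if (t < 0) stop("negative duration t", call. = FALSE)
  e <- exp(-k * q * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (1 - 1 / k) * e
  P
}

#' Specification of a time-dependent evolutionary-rate model
#'
#' Four nested models of how the transition rate of the risk character
#' changes over relative time `t` in `[0, 1]` (0 = root, 1 = present):
#' `null` (constant rate `q`), `delta` (Pagel delta power transform of node
#' depths, exponent `delta`; `delta = 1` is the identity), `linear` (rate
#' `q + s * t`, which must stay positive over the tree), and `two_rate`
#' (rate `q` before breakpoint `B`, second absolute rate `E` after it).
#'
#' @param kind One of `"null"`, `"delta"`, `"linear"`, `"two_rate"`.
#' @param q Baseline transition rate (> 0, per unit relative time).
#' @param delta Power-transform exponent (> 0; `delta` models only).
#' @param s Linear slope (rate units per relative time; `linear` only).
#' @param B Breakpoint in `[0, 1]` (`two_rate` only).
#' @param E Second rate after the breakpoint (> 0; `two_rate` only).
#' @return A `model_spec` object.
#' @export
model_spec <- function(kind = c("null", "delta", "linear", "two_rate"),
                       q, delta = NULL, s = NULL, B = NULL, E = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(q), length(q) == 1L, is.finite(q), q > 0)
  spec <- list(kind = kind, q = q)
  if (kind == "delta") {
    stopifnot(!is.null(delta), is.finite(delta), delta > 0)
    spec$delta <- delta
  } else if (kind == "linear") {
    stopifnot(!is.null(s), is.finite(s))
    if (min(q, q + s) < 0) {
      stop("linear model rate q + s*t is negative somewhere on [0,1]", call. = FALSE)
    }
    spec$s <- s
  } else if (kind == "two_rate") {
    stopifnot(!is.null(B), B >= 0, B <= 1, !is.null(E), is.finite(E), E > 0)
    spec$B <- B
    spec$E <- E
  }
  structure(spec, class = "model_spec")
}

#' Apply a rate model as a branch-length transform
#'
#' Rescales every branch so that running the constant-rate ER process at
#' rate `q` on the transformed tree is equivalent to running the
#' time-dependent model on the original tree: a branch spanning relative
#' times `[t0, t1]` gets effective length `\int_{t0}^{t1} r(t) dt / q`
#' (times the tree's absolute depth). For the delta model the node depths
#' `d` (normalized to `[0, 1]`) are replaced by `d^delta`, which preserves
#' the total depth. Identity cases (`delta = 1`, `s = 0`, `E = q`) return
#' the tree unchanged up to floating point.
#'
#' @param tree Ultrametric `phylo`.
#' @param spec A `model_spec`.
#' @return A `phylo` with effective branch lengths.
#' @export
transform_branches <- function(tree, spec) {
  stopifnot(inherits(spec, "model_spec"))
  validate_phylogeny(tree)
  if (spec$kind == "null") return(tree)
  tt <- relative_times(tree)       # errors if not ultrametric
  total <- max(node_depths(tree))
  t0 <- tt[tree$edge[, 1L]]
  t1 <- tt[tree$edge[, 2L]]
  out <- tree
  out$edge.length <- .effective_lengths(t0, t1, spec) * total
  out
}

# Effective branch length on the relative-time scale for an edge spanning
# [t0, t1]; running rate q on the result equals the time-dependent model.
.effective_lengths <- function(t0, t1, spec) {
  eff <- switch(spec$kind,
    null = t1 - t0,
    delta = t1^spec$delta - t0^spec$delta,
    linear = {
      if (min(spec$q, spec$q + spec$s) < 0) {
        stop("linear rate is negative over part of the tree", call. = FALSE)
      }
      (t1 - t0) + (spec$s / spec$q) * (t1^2 - t0^2) / 2
    },
    two_rate = {
      before <- pmax(0, pmin(t1, spec$B) - t0)
      after <- pmax(0, t1 - pmax(t0, spec$B))
      before + (spec$E / spec$q) * after
    }
  )
  as.numeric(eff)
}

#' Pruning log-likelihood of tip states under the ER Mk model
#'
#' Felsenstein's pruning algorithm on a rooted tree (polytomies allowed):
#' tip partial likelihoods are indicator vectors (a tip with state `NA` is
#' treated as ambiguous, i.e. all ones), each internal node's partial is
#' the product over children of the transition-matrix-propagated child
#' partials, and the likelihood is the root partial averaged over the root
#' prior. Partials are rescaled at every node so long trees do not
#' underflow. A data set that is impossible under the model (e.g. `q = 0`
#' with unequal tip states) returns `-Inf`.
#'
#' @param tree `phylo` with branch lengths (possibly transformed, need not
#'   be ultrametric).
#' @param states Named integer vector in `1..k` (or `coded_states`);
#'   `NA` marks an explicitly ambiguous tip.
#' @param q ER transition rate >= 0.
#' @param k Number of states (default 4).
#' @param root_prior `"uniform"` (the ER stationary distribution) or
#'   `"fitzjohn"` (weights each root state by its conditional likelihood).
#' @return Log-likelihood (natural log), possibly `-Inf`.
#' @export
mk_loglik <- function(tree, states, q, k = 4L,
                      root_prior = c("uniform", "fitzjohn")) {
  root_prior <- match.arg(root_prior)
  if (q < 0) stop("negative rate q", call. = FALSE)
  validate_phylogeny(tree)
  s <- .state_vector(states)
  ntip <- ape::Ntip(tree)
  idx <- match(tree$tip.label, names(s))
  if (anyNA(idx)) {
    stop("tip without state (and not marked ambiguous): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  x <- as.integer(s[idx])
  if (any(!is.na(x) & (x < 1L | x > k))) stop("states must lie in 1..", k, call. = FALSE)
  n_nodes <- ntip + tree$Nnode
  part <- matrix(1, n_nodes, k)
  for (i in seq_len(ntip)) {
    if (!is.na(x[i])) {
      part[i, ] <- 0
      part[i, x[i]] <- 1
    }
  }
  po <- ape::reorder.phylo(tree, "postorder")
  logscale <- 0
  for (i in seq_len(nrow(po$edge))) {
    pa <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    e <- exp(-k * q * po$edge.length[i])
    # P %*% p for the ER closed form: P = e*I + (1-e)/k * J
    msg <- e * part[ch, ] + (1 - e) * mean(part[ch, ])
    m <- max(msg)
    if (m <= 0) return(-Inf)
    part[pa, ] <- part[pa, ] * (msg / m)
    logscale <- logscale + log(m)
  }
  root <- part[ntip + 1L, ]
  lik <- if (root_prior == "uniform") mean(root) else {
    if (sum(root) <= 0) return(-Inf)
    sum(root^2) / sum(root)
  }
  if (lik <= 0) return(-Inf)
  log(lik) + logscale
}

# Precompiled pruning machinery for repeated likelihood evaluation on one
# (tree, states) pair: postorder edge arrays, relative edge spans and tip
# indicator partials are computed once; the returned closure evaluates the
# log-likelihood of a model_spec directly from the effective edge lengths.
.mk_machine <- function(tree, states, k = 4L, root_prior = "uniform") {
  validate_phylogeny(tree)
  s <- .state_vector(states)
  ntip <- ape::Ntip(tree)
  idx <- match(tree$tip.label, names(s))
  if (anyNA(idx)) {
    stop("tip without state: ", paste(tree$tip.label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  x <- as.integer(s[idx])
  tt <- relative_times(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  pa <- po$edge[, 1L]; ch <- po$edge[, 2L]
  t0 <- tt[pa]; t1 <- tt[ch]
  n_nodes <- ntip + tree$Nnode
  part0 <- matrix(1, n_nodes, k)
  for (i in seq_len(ntip)) {
    if (!is.na(x[i])) { part0[i, ] <- 0; part0[i, x[i]] <- 1 }
  }
  fitzjohn <- identical(root_prior, "fitzjohn")
  function(spec) {
    el <- tryCatch(.effective_lengths(t0, t1, spec), error = function(e) NULL)
    if (is.null(el)) return(-Inf)
    .er_prune_cpp(pa, ch, el, spec$q, k, part0, ntip + 1L, fitzjohn)
  }
}
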