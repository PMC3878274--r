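#' Mean pairwise disparity of a set of trait values
#'
#' The disparity of a set of tip values is the mean over unordered pairs of
#' either the squared difference (`avg_sq`, the convention of the
#' disparity-through-time literature) or the absolute difference
#' (`avg_abs`). A single value has disparity 0.
#'
#' @param values Numeric vector (integer risk codes or continuous traits).
#' @param metric `"avg_sq"` or `"avg_abs"`.
#' @return Non-negative scalar.
#' @export
disparity <- function(values, metric = c("avg_sq", "avg_abs")) {
  metric <- match.arg(metric)
  values <- as.numeric(values)
  n <- length(values)
  if (n == 0L) stop("disparity of an empty set is undefined", call. = FALSE)
  if (n == 1L) return(0)
  n_pairs <- n * (n - 1) / 2
  if (metric == "avg_sq") {
    # sum_{i<j} (x_i - x_j)^2 = n * sum(x^2) - (sum x)^2
    (n * sum(values^2) - sum(values)^2) / n_pairs
  } else {
    # sorted-order identity: sum_{i<j} |x_i - x_j| = sum_i (2i - n - 1) x_(i)
    s <- sort(values)
    sum((2 * seq_len(n) - n - 1) * s) / n_pairs
  }
}

#' Relative disparity-through-time curve
#'
#' Evaluates, at the root and at each internal-node time of an ultrametric
#' tree, the average disparity of the lineages crossing that time, relative
#' to the disparity of the whole clade. A lineage crossing time `t` is an
#' edge whose parent is older than `t` and whose child is at or below `t`;
#' its disparity is that of the tip values descending through it (a single
#' tip contributes 0). Node times that coincide are evaluated once. The
#' curve starts at exactly 1 at the root (the single root lineage spans the
#' whole clade) and values near 0 toward the present indicate that
#' variation lies between rather than within subclades — phylogenetic
#' conservatism of the trait.
#'
#' @param tree Ultrametric `phylo`.
#' @param states Named vector of tip values or a `coded_states` object
#'   covering every tip.
#' @param metric Disparity metric, see [disparity()].
#' @return A `dtt_curve` object: list with `times` (relative times in
#'   `[0, 1)`, root first), `observed`, `metric`.
#' @export
relative_disparity_curve <- function(tree, states, metric = c("avg_sq", "avg_abs")) {
  metric <- match.arg(metric)
  x <- .tip_values_in_order(tree, states)
  total <- disparity(x, metric)
  if (total <= 0) stop("no variation in states: whole-tree disparity is 0", call. = FALSE)
  tt <- relative_times(tree)
  obs <- .dtt_values(tree, x, tt, total, metric)
  structure(list(times = obs$times, observed = obs$values, metric = metric),
            class = "dtt_curve")
}

# Shared curve evaluator; returns values already standardized by `total`.
.dtt_values <- function(tree, x, tt, total, metric) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  below <- vector("list", n_nodes)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  node_disp <- numeric(n_nodes)
  for (v in seq_len(n_nodes)) {
    node_disp[v] <- if (length(below[[v]]) == 1L) 0 else disparity(x[below[[v]]], metric)
  }
  internal <- (ntip + 1L):n_nodes
  times <- sort(unique(tt[internal]))
  if (times[1L] != 0) times <- c(0, times)  # root is always the first point
  vals <- numeric(length(times))
  vals[1L] <- 1
  pa_t <- tt[po$edge[, 1L]]
  ch_t <- tt[po$edge[, 2L]]
  for (j in seq_along(times)[-1L]) {
    u <- times[j]
    crossing <- pa_t < u & ch_t >= u
    vals[j] <- mean(node_disp[po$edge[crossing, 2L]]) / total
  }
  list(times = times, values = vals)
}

.tip_values_in_order <- function(tree, states) {
  s <- .state_vector(states)
  idx <- match(tree$tip.label, names(s))
  if (anyNA(idx)) {
    stop("tips without states: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  as.numeric(s[idx])
}

#' Randomization null for the DTT curve
#'
#' Generates `n_sim` null data sets, recomputes the relative disparity
#' curve for each on the same tree and time grid, and summarizes them as a
#' pointwise quantile envelope. Two null models are available: `bm_sim`
#' (the convention of the DTT literature) estimates a Brownian-motion rate
#' from the observed values by maximum likelihood and simulates continuous
#' tip data under it; `tip_shuffle` permutes the observed values across
#' tips, destroying phylogenetic structure while keeping the state
#' composition fixed.
#'
#' @param tree Ultrametric `phylo`.
#' @param states Tip values (named vector or `coded_states`).
#' @param n_sim Number of null replicates (default 1000).
#' @param null_method `"bm_sim"` or `"tip_shuffle"`.
#' @param seed Integer seed; identical seeds give identical envelopes.
#' @param quantiles Lower/upper envelope quantiles (default 2.5% / 97.5%).
#' @param metric Disparity metric.
#' @return A `dtt_curve` with additional fields `null_curves`
#'   (`n_sim` x time matrix), `null_median`, `lo`, `hi`, `n_sim`,
#'   `null_method`.
#' @export
dtt_null <- function(tree, states, n_sim = 1000L,
                     null_method = c("bm_sim", "tip_shuffle"), seed = NULL,
                     quantiles = c(0.025, 0.975), metric = c("avg_sq", "avg_abs")) {
  null_method <- match.arg(null_method)
  metric <- match.arg(metric)
  stopifnot(n_sim >= 1L, length(quantiles) == 2L, quantiles[1L] < quantiles[2L])
  curve <- relative_disparity_curve(tree, states, metric)
  x <- .tip_values_in_order(tree, states)
  tt <- relative_times(tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  if (null_method == "bm_sim") {
    rate <- bm_rate_ml(tree, x)
    draw <- function() .bm_tips(tree, rate)
  } else {
    xs <- x
    draw <- function() sample(xs)
  }
  nt <- length(curve$times)
  null_curves <- matrix(NA_real_, n_sim, nt)
  for (s in seq_len(n_sim)) {
    y <- draw()
    tot <- disparity(y, metric)
    if (tot <= 0) {            # a permuted constant set cannot occur; BM a.s. varies
      null_curves[s, ] <- c(1, rep(0, nt - 1L))
    } else {
      null_curves[s, ] <- .dtt_values(tree, y, tt, tot, metric)$values
    }
  }
  curve$null_curves <- null_curves
  curve$null_median <- apply(null_curves, 2L, stats::median)
  curve$lo <- apply(null_curves, 2L, stats::quantile, probs = quantiles[1L])
  curve$hi <- apply(null_curves, 2L, stats::quantile, probs = quantiles[2L])
  curve$n_sim <- n_sim
  curve$null_method <- null_method
  curve
}

#' Maximum-likelihood Brownian-motion rate
#'
#' ML estimate of the BM rate for continuous tip values on a tree:
#' \eqn{\hat\sigma^2 = (x-\hat\mu)' C^{-1} (x-\hat\mu)/n} with `C` the
#' phylogenetic covariance (shared path length) matrix and \eqn{\hat\mu}
#' the GLS root state.
#'
#' @param tree `phylo` with branch lengths.
#' @param x Tip values in `tree$tip.label` order (or named).
#' @return Scalar rate (per unit branch length).
#' @export
bm_rate_ml <- function(tree, x) {
  if (!is.null(names(x))) x <- x[tree$tip.label]
  C <- ape::vcv(tree)
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  as.numeric((x - mu) %*% Ci %*% (x - mu)) / n
}

#' Classify each time point against the null envelope
#'
#' Applies the decision rule used throughout this analysis: an observed
#' relative-disparity value above the upper envelope quantile is reported
#' as `conservatism`, below the lower quantile as `overdispersion`, and
#' `ns` otherwise. Also reports an MDI-style summary, the mean of observed
#' minus null-median across the curve (positive when the observed curve
#' sits above the null).
#'
#' @param curve A `dtt_curve` from [dtt_null()].
#' @return List with `table` (data.frame `time`, `observed`, `null_median`,
#'   `lo`, `hi`, `call`) and `mdi` (scalar).
#' @export
conservatism_report <- function(curve) {
  stopifnot(inherits(curve, "dtt_curve"))
  if (is.null(curve$lo)) stop("curve has no null envelope; run dtt_null() first", call. = FALSE)
  call <- ifelse(curve$observed > curve$hi, "conservatism",
                 ifelse(curve$observed < curve$lo, "overdispersion", "ns"))
  tab <- data.frame(time = curve$times, observed = curve$observed,
                    null_median = curve$null_median, lo = curve$lo, hi = curve$hi,
                    call = call, stringsAsFactors = FALSE)
  list(table = tab, mdi = mean(curve$observed - curve$null_median))
}

#' @export
plot.dtt_curve <- function(x, ...) {
  plot(x$times, x$observed, type = "l", lwd = 2, ylim = c(0, max(1.05, x$observed)),
       xlab = "relative time (0 = root, 1 = present)",
       ylab = "relative disparity", ...)
  if (!is.null(x$null_median)) {
    graphics::polygon(c(x$times, rev(x$times)), c(x$lo, rev(x$hi)),
                      col = grDevices::adjustcolor("grey", 0.5), border = NA)
    graphics::lines(x$times, x$null_median, lty = 2)
    graphics::lines(x$times, x$observed, lwd = 2)
  }
  invisible(x)
}
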