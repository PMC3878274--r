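#' Options controlling maximum-likelihood fitting
#'
#' @param n_starts Number of random multi-starts (seeded).
#' @param grid_n Breakpoint profile-grid size for the two-rate model
#'   (default 101 points on `[0, 1]`; the breakpoint likelihood is only
#'   piecewise smooth, so it is profiled on a grid and then refined
#'   locally).
#' @param tol Relative convergence tolerance.
#' @param seed Seed for the random starts.
#' @param q_range,delta_range Box bounds for the positive parameters
#'   (optimized on the log scale).
#' @param root_prior Root prior passed to [mk_loglik()].
#' @param aic_convention `"reduced"` counts only parameters beyond the
#'   baseline rate; `"standard"` counts all free parameters.
#' @return List of options for [fit_model()].
#' @export
fit_opts <- function(n_starts = 5L, grid_n = 101L, tol = 1e-8, seed = 1L,
                     q_range = c(1e-4, 1e3), delta_range = c(1e-2, 1e2),
                     root_prior = "uniform", aic_convention = "reduced") {
  list(n_starts = n_starts, grid_n = grid_n, tol = tol, seed = seed,
       q_range = q_range, delta_range = delta_range, root_prior = root_prior,
       aic_convention = aic_convention)
}

#' Fit a time-dependent ER Mk model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free parameters:
#' `q` alone (null), plus `delta`, `s`, or `(B, E)`. Positive parameters
#' are optimized on the log scale with seeded random multi-starts; the
#' two-rate breakpoint `B` is profiled over a grid (warm-starting `(q, E)`
#' along it) and the best grid point is then refined by a joint local
#' search. The tree is rescaled to unit depth internally, so `q` is
#' reported per unit of relative time (root = 0, present = 1).
#'
#' @param tree Ultrametric `phylo`.
#' @param states Tip states (named vector or `coded_states`).
#' @param kind Model kind, see [model_spec()].
#' @param opts See [fit_opts()].
#' @return A `fit_result`: list with `kind`, `logL`, `estimates`,
#'   `k_extra`, `AIC`, `converged`, `n_starts`, `diagnostics`.
#' @export
fit_model <- function(tree, states, kind = c("null", "delta", "linear", "two_rate"),
                      opts = fit_opts()) {
  kind <- match.arg(kind)
  validate_phylogeny(tree)
  total <- max(node_depths(tree))
  tree$edge.length <- tree$edge.length / total   # unit depth; q per relative time
  s <- .state_vector(states)
  rp <- opts$root_prior
  lqr <- log(opts$q_range)
  ldr <- log(opts$delta_range)
  set.seed(opts$seed)
  rand_lq <- function() stats::runif(1, log(0.01), log(100))
  ctl <- list(rel.tol = opts$tol, iter.max = 500L, eval.max = 2000L)
  diagnostics <- list()
  machine <- .mk_machine(tree, s, root_prior = rp)
  nll <- function(spec) {
    ll <- tryCatch(machine(spec), error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # the non-null models nest the null at their identity point, so the null
  # MLE is always a valid (and often excellent) first start
  lq0 <- stats::optimize(function(lq) nll(model_spec("null", q = exp(lq))),
                         lower = lqr[1], upper = lqr[2], tol = 1e-10)$minimum

  run_starts <- function(make_par0, obj, lower, upper) {
    best <- NULL
    for (st in seq_len(opts$n_starts)) {
      p0 <- make_par0(st)
      res <- tryCatch(stats::nlminb(p0, obj, lower = lower, upper = upper, control = ctl),
                      error = function(e) NULL)
      if (!is.null(res) && is.finite(res$objective) && res$objective < 1e9 &&
          (is.null(best) || res$objective < best$objective)) best <- res
    }
    best
  }

  if (kind == "null") {
    obj <- function(p) nll(model_spec("null", q = exp(p[1])))
    best <- run_starts(function(st) if (st == 1L) lq0 else rand_lq(),
                       obj, lqr[1], lqr[2])
    if (is.null(best)) stop("all optimizer starts failed for the null model", call. = FALSE)
    est <- c(q = exp(best$par[1]))
    k_extra <- 0L
  } else if (kind == "delta") {
    obj <- function(p) nll(model_spec("delta", q = exp(p[1]), delta = exp(p[2])))
    best <- run_starts(function(st) if (st == 1L) c(lq0, 0)
                       else c(rand_lq(), stats::runif(1, log(0.1), log(10))),
                       obj, c(lqr[1], ldr[1]), c(lqr[2], ldr[2]))
    if (is.null(best)) stop("all optimizer starts failed for the delta model", call. = FALSE)
    est <- c(q = exp(best$par[1]), delta = exp(best$par[2]))
    k_extra <- 1L
  } else if (kind == "linear") {
    # feasibility r(t) = q + s*t >= 1e-8 on [0,1], enforced by sentinel
    obj <- function(p) {
      q <- exp(p[1]); sl <- p[2]
      if (min(q, q + sl) < 1e-8) return(1e10 + abs(min(q, q + sl)))
      nll(model_spec("linear", q = q, s = sl))
    }
    best <- run_starts(function(st) if (st == 1L) c(lq0, 0)
                       else { lq <- rand_lq(); c(lq, stats::runif(1, -exp(lq) / 2, exp(lq))) },
                       obj, c(lqr[1], -Inf), c(lqr[2], Inf))
    if (is.null(best)) stop("all optimizer starts failed for the linear model", call. = FALSE)
    est <- c(q = exp(best$par[1]), s = best$par[2])
    k_extra <- 1L
  } else {
    # two_rate: profile B on a grid with warm starts, then refine jointly
    grid <- seq(0, 1, length.out = opts$grid_n)
    obj_at_B <- function(B) function(p)
      nll(model_spec("two_rate", q = exp(p[1]), B = B, E = exp(p[2])))
    warm <- NULL; best <- NULL; best_B <- NA_real_
    profile <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      B <- grid[gi]
      o <- obj_at_B(B)
      # q = E is a flat ridge (the null model for every B) and saturated
      # rates are a broad basin, so a warm start alone can stall; every
      # grid point also tries slow-then-fast and fast-then-slow anchors
      anchors <- list(c(log(0.1), log(10)), c(log(10), log(0.1)))
      starts <- if (gi == 1L) {
        c(list(c(lq0, lq0)), anchors,
          lapply(seq_len(max(0L, opts$n_starts - 3L)),
                 function(st) c(rand_lq(), rand_lq())))
      } else {
        c(list(warm), anchors)
      }
      cand <- NULL
      for (p0 in starts) {
        r1 <- tryCatch(stats::nlminb(p0, o, lower = c(lqr[1], lqr[1]),
                                     upper = c(lqr[2], lqr[2]), control = ctl),
                       error = function(e) NULL)
        if (!is.null(r1) && is.finite(r1$objective) &&
            (is.null(cand) || r1$objective < cand$objective)) cand <- r1
      }
      if (is.null(cand) || !is.finite(cand$objective)) { profile[gi] <- NA; next }
      warm <- cand$par
      profile[gi] <- cand$objective
      if (is.null(best) || cand$objective < best$objective) { best <- cand; best_B <- B }
    }
    if (is.null(best)) stop("all optimizer starts failed for the two-rate model", call. = FALSE)
    step <- if (length(grid) > 1L) diff(grid[1:2]) else 0.5
    refine_obj <- function(p) {
      B <- p[3]
      obj_at_B(B)(p[1:2])
    }
    ref <- tryCatch(stats::nlminb(c(best$par, best_B), refine_obj,
                                  lower = c(lqr[1], lqr[1], max(0, best_B - step)),
                                  upper = c(lqr[2], lqr[2], min(1, best_B + step)),
                                  control = ctl),
                    error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$objective) && ref$objective <= best$objective) {
      est <- c(q = exp(ref$par[1]), B = ref$par[3], E = exp(ref$par[2]))
      best <- ref
    } else {
      est <- c(q = exp(best$par[1]), B = best_B, E = exp(best$par[2]))
    }
    k_extra <- 2L
    diagnostics$B_profile <- data.frame(B = grid, neg_loglik = profile)
    diagnostics$B_at_boundary <- est[["B"]] <= step / 2 || est[["B"]] >= 1 - step / 2
  }

  logL <- -best$objective
  structure(list(
    kind = kind, logL = logL, estimates = est, k_extra = k_extra,
    AIC = aic(logL, k_extra, opts$aic_convention),
    converged = best$convergence == 0 || grepl("converg", best$message, ignore.case = TRUE),
    n_starts = opts$n_starts, diagnostics = diagnostics
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s model: logL = %.4f, AIC = %.4f (%s)\n", x$kind, x$logL, x$AIC,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$estimates, 5))
  invisible(x)
}

#' Akaike Information Criterion
#'
#' Under the default `reduced` convention only the parameters beyond the
#' shared baseline transition rate are counted (null 0, delta 1, linear 1,
#' two-rate 2), so the null model's AIC is exactly `-2 logL` — the
#' convention of the comparison this package reproduces. The `standard`
#' convention counts every free parameter, including the baseline rate.
#'
#' @param logL Maximized log-likelihood (finite).
#' @param k_extra Number of parameters beyond the baseline rate (>= 0).
#' @param convention `"reduced"` or `"standard"`.
#' @return AIC value.
#' @export
aic <- function(logL, k_extra, convention = c("reduced", "standard")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(logL), k_extra >= 0, k_extra == round(k_extra))
  k <- if (convention == "reduced") k_extra else k_extra + 1
  -2 * logL + 2 * k
}

#' Model comparison table
#'
#' @param fits List of `fit_result` objects.
#' @return Data frame sorted by ascending AIC with columns `model`, `logL`,
#'   `q`, `params` (extra parameter estimates, formatted), `AIC`,
#'   `delta_AIC`, `best`; the attribute `close_competition` is `TRUE` when
#'   the runner-up is within 2 AIC units of the best model (in which case
#'   the simpler model cannot be rejected).
#' @export
model_table <- function(fits) {
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "fit_result")))
  rows <- lapply(fits, function(f) {
    extra <- f$estimates[setdiff(names(f$estimates), "q")]
    data.frame(model = f$kind, logL = f$logL, q = unname(f$estimates[["q"]]),
               params = if (length(extra) == 0L) "-" else
                 paste(sprintf("%s=%.4g", names(extra), extra), collapse = ", "),
               AIC = f$AIC, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC), , drop = FALSE]
  tab$delta_AIC <- tab$AIC - tab$AIC[1L]
  tab$best <- seq_len(nrow(tab)) == 1L
  rownames(tab) <- NULL
  attr(tab, "close_competition") <- nrow(tab) >= 2L && tab$delta_AIC[2L] < 2
  tab
}
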