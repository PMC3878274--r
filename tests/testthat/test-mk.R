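test_that("the ER transition matrix matches its closed form and limits", {
  expect_equal(transition_matrix_er(0.7, 0), diag(4))
  expect_equal(transition_matrix_er(5, 1e6), matrix(0.25, 4, 4))
  P <- transition_matrix_er(0.25, 1)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-1))
  expect_equal(P[1, 2], (1 - exp(-1)) / 4)
  expect_error(transition_matrix_er(-1, 1), "negative")
  expect_error(transition_matrix_er(1, -1), "negative")
})

test_that("the closed form agrees with a generic matrix exponential on a grid", {
  for (q in c(0, 0.1, 0.25, 1, 3)) {
    for (t in c(0, 0.01, 0.5, 1, 4)) {
      P <- transition_matrix_er(q, t)
      expect_equal(P, er_matexpo_oracle(q, t), tolerance = 1e-10)
      expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
    }
  }
  # Chapman-Kolmogorov: P(s) P(t) = P(s + t)
  for (q in c(0.3, 1.7)) {
    expect_equal(transition_matrix_er(q, 0.4) %*% transition_matrix_er(q, 0.9),
                 transition_matrix_er(q, 1.3), tolerance = 1e-10)
  }
})

test_that("branch transforms have exact identity points and piecewise integrals", {
  tr <- simulate_yule(12, seed = 8)
  expect_equal(transform_branches(tr, model_spec("delta", q = 1, delta = 1))$edge.length,
               tr$edge.length)
  expect_equal(transform_branches(tr, model_spec("linear", q = 1, s = 0))$edge.length,
               tr$edge.length)
  expect_equal(transform_branches(tr, model_spec("two_rate", q = 0.8, B = 0.5,
                                                 E = 0.8))$edge.length,
               tr$edge.length)

  # branch spanning [0.4, 0.6] with B = 0.5, E = 2q: multiplier (0.1 + 0.2)/0.2
  cat4 <- parse_newick("(((A:0.4,B:0.4):0.2,C:0.6):0.4,D:1);")
  tw <- transform_branches(cat4, model_spec("two_rate", q = 1, B = 0.5, E = 2))
  span_edge <- which(cat4$edge.length == 0.2)
  expect_equal(tw$edge.length[span_edge], 0.3)

  # delta replaces node depths by d^delta
  dl <- transform_branches(cat4, model_spec("delta", q = 1, delta = 2))
  expect_equal(node_depths(dl), node_depths(cat4)^2)

  expect_error(model_spec("linear", q = 1, s = -2), "negative")
  expect_error(model_spec("two_rate", q = 1, B = 1.5, E = 1))
})

test_that("pruning handles zero rates, impossible data and bad input", {
  two <- parse_newick("(A:1,B:1);")
  expect_equal(mk_loglik(two, c(A = 2, B = 2), q = 0), log(1 / 4))
  expect_identical(mk_loglik(two, c(A = 2, B = 3), q = 0), -Inf)
  expect_error(mk_loglik(two, c(A = 2), q = 1), "without state")
  expect_error(mk_loglik(two, c(A = 2, B = 9), q = 1), "1..4")
  expect_error(mk_loglik(two, c(A = 2, B = 2), q = -1), "negative")
  # ambiguous tip: likelihood sums over its states
  expect_equal(mk_loglik(two, c(A = 2, B = NA), q = 0.5), log(1 / 4))
})

test_that("pruning agrees with exhaustive state enumeration on small trees", {
  set.seed(55)
  for (i in 1:10) {
    tr <- ape::rtree(sample(3:6, 1))
    st <- random_states(tr)
    q <- stats::runif(1, 0, 2)
    expect_equal(mk_loglik(tr, st, q), brute_mk_loglik(tr, st, q),
                 tolerance = 1e-10)
  }
})

test_that("pruning supports polytomies and is invariant to relabeling", {
  poly <- parse_newick("(A:1,B:1,C:1,(D:0.5,E:0.5):0.5);")
  st <- c(A = 1, B = 2, C = 2, D = 4, E = 4)
  q <- 0.6
  expect_equal(mk_loglik(poly, st, q), brute_mk_loglik(poly, st, q),
               tolerance = 1e-10)

  tr <- ape::rtree(8)
  st <- random_states(tr)
  ll <- mk_loglik(tr, st, 0.4)
  # permute tip labels together with their states
  perm <- sample(ape::Ntip(tr))
  tr2 <- tr
  tr2$tip.label <- tr$tip.label[perm]
  st2 <- st
  names(st2) <- names(st)[perm]
  expect_equal(mk_loglik(tr2, st2, 0.4), ll, tolerance = 1e-12)
  # rotating children does not change the likelihood
  tr3 <- ape::rotate(tr, ape::Ntip(tr) + 1L)
  expect_equal(mk_loglik(tr3, st, 0.4), ll, tolerance = 1e-12)
})

test_that("AIC follows the reduced parameter-count convention by default", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-63.17, 0), 126.34)
  expect_equal(aic(-60.73, 2), 125.46)
  expect_equal(aic(-10, 1, convention = "standard"), 24)
  expect_equal(aic(-10, 1, convention = "reduced"), 22)
  expect_error(aic(Inf, 0))
  expect_error(aic(-1, -1))
})

test_that("fitted models respect nesting and populate the comparison table", {
  tr <- simulate_yule(60, seed = 14)
  st <- simulate_mk(tr, model_spec("null", q = 0.8), seed = 15)
  opts <- fit_opts(n_starts = 2, grid_n = 21, seed = 3)
  fits <- lapply(c("null", "delta", "linear", "two_rate"),
                 function(kk) fit_model(tr, st, kk, opts))
  logl <- vapply(fits, function(f) f$logL, numeric(1))
  expect_true(all(logl[2:4] >= logl[1] - 1e-6))
  expect_equal(vapply(fits, function(f) f$k_extra, integer(1)), c(0L, 1L, 1L, 2L))
  for (f in fits) expect_equal(f$AIC, -2 * f$logL + 2 * f$k_extra)

  tab <- model_table(fits)
  expect_equal(nrow(tab), 4)
  expect_false(is.unsorted(tab$AIC))
  expect_equal(tab$delta_AIC[1], 0)
  expect_true(tab$best[1])

  single <- model_table(fits[1])
  expect_equal(single$delta_AIC, 0)
  expect_true(single$best)
})

test_that("the two-rate fit flags boundary breakpoints in its diagnostics", {
  tr <- simulate_yule(40, seed = 91)
  st <- simulate_mk(tr, model_spec("null", q = 0.5), seed = 92)
  f <- fit_model(tr, st, "two_rate", fit_opts(n_starts = 1, grid_n = 11, seed = 1))
  expect_type(f$diagnostics$B_at_boundary, "logical")
  expect_s3_class(f$diagnostics$B_profile, "data.frame")
  expect_equal(nrow(f$diagnostics$B_profile), 11)
})
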