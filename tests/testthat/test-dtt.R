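test_that("disparity matches hand values and the pair-enumeration oracle", {
  expect_equal(disparity(c(4, 4, 4)), 0)
  expect_equal(disparity(c(1, 4)), 9)
  expect_equal(disparity(c(1, 2, 3, 4)), 10 / 3)
  expect_equal(disparity(5), 0)
  expect_error(disparity(numeric(0)), "empty")

  set.seed(31)
  for (i in 1:25) {
    x <- stats::runif(sample(2:40, 1), -5, 5)
    expect_equal(disparity(x, "avg_sq"), pairwise_disparity_oracle(x, TRUE))
    expect_equal(disparity(x, "avg_abs"), pairwise_disparity_oracle(x, FALSE))
  }
})

test_that("the relative disparity curve starts at 1 and matches 4-tip hand values", {
  t4 <- balanced4()
  clustered <- relative_disparity_curve(t4, c(A = 1, B = 1, C = 4, D = 4))
  expect_identical(clustered$observed[1], 1)
  expect_equal(clustered$times, c(0, 0.5))
  # inside the daughter clades both subclade disparities are 0
  expect_equal(clustered$observed[2], 0)

  alternating <- relative_disparity_curve(t4, c(A = 1, B = 4, C = 1, D = 4))
  # each daughter clade has disparity 9; whole-tree disparity of (1,4,1,4) is 6
  expect_equal(alternating$observed[2], 1.5)

  expect_error(relative_disparity_curve(t4, c(A = 2, B = 2, C = 2, D = 2)),
               "no variation")
})

test_that("curve values are non-negative, times lie in [0,1), tip order is irrelevant", {
  for (r in 1:5) {
    tr <- simulate_yule(24, seed = 70 + r)
    st <- random_states(tr)
    if (disparity(st) == 0) next
    cv <- relative_disparity_curve(tr, st)
    expect_true(all(cv$observed >= 0))
    expect_true(all(cv$times >= 0 & cv$times < 1))
    expect_true(!is.unsorted(cv$times))
    perm <- sample(names(st))
    cv2 <- relative_disparity_curve(tr, st[perm])
    expect_equal(cv2$observed, cv$observed)
  }
})

test_that("null curves are seed-reproducible and start at 1", {
  tr <- simulate_yule(16, seed = 3)
  st <- random_states(tr)
  a <- dtt_null(tr, st, n_sim = 10, seed = 123)
  b <- dtt_null(tr, st, n_sim = 10, seed = 123)
  expect_identical(a$null_curves, b$null_curves)
  expect_equal(unname(a$null_curves[, 1]), rep(1, 10))
  shuf <- dtt_null(tr, st, n_sim = 10, null_method = "tip_shuffle", seed = 5)
  expect_equal(unname(shuf$null_curves[, 1]), rep(1, 10))
  expect_true(all(shuf$null_curves >= 0))
})

test_that("the ML Brownian rate is exact on a two-tip star", {
  # two tips at depth 1, independent: x ~ N(mu, rate); MLE has a closed form
  tr <- parse_newick("(A:1,B:1);")
  x <- c(A = 0, B = 2)
  # C = I, mu-hat = 1, rate-hat = ((0-1)^2 + (2-1)^2)/2 = 1
  expect_equal(bm_rate_ml(tr, x), 1)
})

test_that("envelope classification follows the observed-vs-null rule", {
  mk_curve <- function(obs, lo, hi, med) {
    structure(list(times = seq_along(obs) - 1, observed = obs, lo = lo, hi = hi,
                   null_median = med, null_curves = matrix(med, 2, length(obs),
                                                           byrow = TRUE)),
              class = "dtt_curve")
  }
  flat <- mk_curve(obs = c(1, 0.5), lo = c(0.9, 0.2), hi = c(1.1, 0.8),
                   med = c(1, 0.5))
  expect_equal(conservatism_report(flat)$table$call, c("ns", "ns"))
  expect_equal(conservatism_report(flat)$mdi, 0)

  high <- mk_curve(obs = c(1.2, 0.9), lo = c(0.9, 0.2), hi = c(1.1, 0.8),
                   med = c(1, 0.5))
  expect_equal(conservatism_report(high)$table$call,
               c("conservatism", "conservatism"))
  expect_gt(conservatism_report(high)$mdi, 0)

  # clade-clustered states sit at the low end of the permutation null, so by
  # the observed-above-null rule they are never reported as conservatism
  t4 <- balanced4()
  cv <- dtt_null(t4, c(A = 1, B = 1, C = 4, D = 4), n_sim = 1000,
                 null_method = "tip_shuffle", seed = 17)
  rep4 <- conservatism_report(cv)
  expect_false(rep4$table$call[2] == "conservatism")
  expect_lte(rep4$mdi, 0)
})
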