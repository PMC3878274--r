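test_that("Newick parsing builds valid trees and rejects bad input", {
  tr <- parse_newick("(A:1,B:1):0;")
  expect_s3_class(tr, "phylo")
  d <- node_depths(tr)
  expect_equal(unname(d[c("A", "B")]), c(1, 1))
  expect_true(is_ultrametric(tr))

  tr3 <- parse_newick("((A:1,B:1):1,C:2):0;")
  d3 <- node_depths(tr3)
  expect_equal(unname(d3[c("A", "B", "C")]), c(2, 2, 2))

  expect_warning(nolen <- parse_newick("((A,B),C);"), "branch lengths")
  expect_true(all(nolen$edge.length == 0))
  expect_error(parse_newick("((A:1,B:1):1,A:2);"), "duplicate")
  expect_error(parse_newick("((A:1,B:1"), "parse")
})

test_that("Newick writing round-trips topology and lengths, keeps zero lengths", {
  two <- parse_newick("(A:1,B:1);")
  s <- write_newick(two)
  expect_match(s, "A:1")
  expect_match(s, "B:1")
  zero <- parse_newick("(A:0,B:1);")
  expect_match(write_newick(zero), "A:0")

  set.seed(11)
  for (i in 1:100) {
    tr <- ape::rtree(sample(3:20, 1))
    back <- parse_newick(write_newick(tr))
    expect_true(ape::all.equal.phylo(tr, back, use.edge.length = TRUE,
                                     tolerance = 1e-8))
  }
})

test_that("node depths increase from root to tips and relative times hit [0,1]", {
  tr <- simulate_yule(20, seed = 5)
  d <- node_depths(tr)
  for (i in seq_len(nrow(tr$edge))) {
    expect_gte(d[tr$edge[i, 2]], d[tr$edge[i, 1]])
  }
  rt <- relative_times(tr)
  expect_equal(unname(rt[ape::Ntip(tr) + 1L]), 0)
  expect_equal(unname(rt[seq_len(ape::Ntip(tr))]), rep(1, 20))

  uneven <- parse_newick("((A:1,B:2):1,C:2);")
  expect_false(is_ultrametric(uneven, tol = 1e-9))
  expect_error(relative_times(uneven), "ultrametric")
})

test_that("majority-rule consensus keeps majority clades and averages lengths", {
  t1 <- parse_newick("((A:1,B:3):1,C:2);")
  t2 <- parse_newick("((A:1,B:1):3,C:2);")
  t3 <- parse_newick("((A:1,C:1):1,B:2);")

  # unanimous input reproduces the tree exactly
  same <- consensus_tree(c(t1, t1, t1))
  expect_true(ape::all.equal.phylo(same, t1, use.edge.length = TRUE))

  # 2-vs-1: clade AB (freq 2/3) survives, AC (freq 1/3) does not
  cns <- consensus_tree(c(t1, t2, t3))
  expect_true(ape::all.equal.phylo(cns, t1, use.edge.length = FALSE))
  # AB stem averaged over the two trees containing it: (1 + 3) / 2
  ab_node <- ape::getMRCA(cns, c("A", "B"))
  ab_edge <- which(cns$edge[, 2] == ab_node)
  expect_equal(cns$edge.length[ab_edge], 2)
  # terminal branches averaged over all three trees
  expect_equal(cns$edge.length[cns$edge[, 2] == which(cns$tip.label == "B")],
               mean(c(3, 1, 2)))

  expect_error(consensus_tree(list()), "empty")
  t4 <- parse_newick("((A:1,B:1):1,D:2);")
  expect_error(consensus_tree(c(t1, t4)), "mismatched")
})

test_that("every consensus clade is recounted above the threshold in the inputs", {
  set.seed(21)
  base <- simulate_yule(12, seed = 21)
  trees <- lapply(1:9, function(i) {
    tr <- if (i <= 6) base else ape::rtree(12, tip.label = base$tip.label)
    tr
  })
  class(trees) <- "multiPhylo"
  cns <- consensus_tree(trees, threshold = 0.5)
  part_in <- ape::prop.part(trees)
  labs_in <- attr(part_in, "labels")
  key_in <- vapply(part_in, function(s) paste(sort(labs_in[s]), collapse = "|"), "")
  freq_in <- attr(part_in, "number") / length(trees)
  part_out <- ape::prop.part(cns)
  labs_out <- attr(part_out, "labels")
  for (cl in part_out) {
    key <- paste(sort(labs_out[cl]), collapse = "|")
    if (length(cl) == ape::Ntip(cns)) next  # root clade is not an input edge
    expect_gt(freq_in[match(key, key_in)], 0.5)
  }
})

test_that("penalized-likelihood dating returns ultrametric trees of the requested age", {
  for (r in 1:5) {
    tr <- simulate_yule(12, seed = 30 + r)
    set.seed(40 + r)
    tr$edge.length <- tr$edge.length * exp(stats::rnorm(length(tr$edge.length), 0, 0.4))
    dt <- date_tree_pl(tr)
    expect_true(is_ultrametric(dt, tol = 1e-6))
    expect_equal(max(node_depths(dt)), 1, tolerance = 1e-9)
  }
  neg <- simulate_yule(5, seed = 1)
  neg$edge.length[1] <- -0.1
  expect_error(date_tree_pl(neg), "negative")
})

test_that("dating an already-ultrametric tree preserves relative node ages", {
  tr <- simulate_yule(10, seed = 77)
  dt <- date_tree_pl(tr, root_age = 1)
  expect_equal(node_depths(dt), node_depths(tr), tolerance = 1e-5)
})

test_that("dating objective matches a brute-force grid minimization on a caterpillar", {
  tr <- parse_newick("((A:1,B:2):1,C:3);")
  dt <- date_tree_pl(tr, smoothing = 1)
  got <- attr(dt, "objective")

  # oracle: grid over the single free internal age x; rates solved from the
  # explicit 4x4 quadratic form (edges: AB-stem, A, B, C; pairs (AB,A),(AB,B))
  lam <- 1
  obj_at <- function(x) {
    tt <- c(x, 1 - x, 1 - x, 1)
    b <- c(1, 1, 2, 3)
    A <- diag(tt^2)
    for (chd in 2:3) {
      A[1, 1] <- A[1, 1] + lam
      A[chd, chd] <- A[chd, chd] + lam
      A[1, chd] <- A[1, chd] - lam
      A[chd, 1] <- A[chd, 1] - lam
    }
    r <- solve(A, b * tt)
    sum((b - r * tt)^2) + lam * ((r[1] - r[2])^2 + (r[1] - r[3])^2)
  }
  grid_min <- min(vapply(seq(0.001, 0.999, by = 0.001), obj_at, numeric(1)))
  expect_equal(got, grid_min, tolerance = 1e-5)
  expect_lte(got, grid_min + 1e-8)
})
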