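# Independent oracles and tiny fixtures used across the suite. Everything
# here is deliberately naive (enumeration, direct pair loops, generic matrix
# exponentials) so it cannot share a defect with the package's fast paths.

# Mean pairwise disparity by direct double loop.
pairwise_disparity_oracle <- function(x, squared = TRUE) {
  n <- length(x)
  if (n < 2) return(0)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- x[i] - x[j]
    tot <- tot + if (squared) d^2 else abs(d)
    np <- np + 1
  }
  tot / np
}

# ER transition matrix via a generic matrix exponential of the generator.
er_matexpo_oracle <- function(q, t, k = 4) {
  Q <- matrix(q, k, k)
  diag(Q) <- -(k - 1) * q
  ape::matexpo(Q * t)
}

# Mk likelihood by exhaustive enumeration over all internal-state
# assignments (uniform root prior), feasible for <= 5 internal nodes.
brute_mk_loglik <- function(tree, states, q, k = 4) {
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  Plist <- lapply(tree$edge.length, function(t) er_matexpo_oracle(q, t, k))
  x <- as.integer(states[tree$tip.label])
  grid <- as.matrix(expand.grid(rep(list(1:k), nint)))
  node_state <- function(g, node) if (node <= ntip) x[node] else grid[g, node - ntip]
  total <- 0
  for (g in seq_len(nrow(grid))) {
    p <- 1 / k
    for (i in seq_len(nrow(tree$edge))) {
      p <- p * Plist[[i]][node_state(g, tree$edge[i, 1]), node_state(g, tree$edge[i, 2])]
      if (p == 0) break
    }
    total <- total + p
  }
  log(total)
}

# Balanced 4-tip unit-depth tree used by the DTT hand examples.
balanced4 <- function() {
  parse_newick("((A:0.5,B:0.5):0.5,(C:0.5,D:0.5):0.5);")
}

random_states <- function(tree, k = 4) {
  s <- sample.int(k, ape::Ntip(tree), replace = TRUE)
  names(s) <- tree$tip.label
  s
}
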