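---
title: "Modeling the evolution of extinction risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of extinction risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskevo)
```

`riskevo` treats IUCN Red List categories as an evolving character on a
dated phylogeny. This vignette documents the statistical machinery, the
choices that were genuinely open when the package was designed, the
numerical details that matter in practice, and the limits of what the test
suite can demonstrate.

## The character and its two readings

Categories are coded EN = 1, VU = 2, NT = 3, LC = 4; data-deficient (DD)
species and species with no Red List record are excluded with a logged
reason, and species absent from the tree are dropped with reason
`not-in-tree` (names are matched after normalizing case and
spaces/underscores; there is no fuzzy matching, because a silently wrong
taxonomic merge is worse than a logged exclusion).

The coded states are used in two deliberately different ways:

* **as an ordinal scale** for disparity — the DTT curve needs pairwise
  distances, and squared differences of the integer codes provide them;
* **as unordered labels** for the Markov model — the equal-rates (ER)
  chain is symmetric over categories, so the ordering carries no
  information there anyway.

This dual use is internally consistent precisely because the ER model
ignores the ordering.

## Disparity through time

The disparity of a set of values is the mean over unordered pairs of the
squared difference (`avg_sq`, the default and the convention of the DTT
literature) or the absolute difference (`avg_abs`, offered because "mean
pairwise distance" is ambiguous in common usage). For a clade of one the
disparity is 0.

The curve is evaluated at the root and at every distinct internal-node
relative time $t \in [0, 1)$ of an ultrametric tree. A lineage *crossing*
$t$ is an edge whose parent node is strictly older than $t$ and whose
child is at or below it, so at a branching time the evaluation sees the
clade *just before* it splits. The curve value is the mean subclade
disparity across crossing lineages divided by the whole-clade disparity;
at the root the single crossing lineage is the whole clade, so the curve
starts at exactly 1. The present ($t = 1$) is excluded: every lineage
there is a single tip and the value is identically 0. A whole-tree
disparity of 0 (all species in one category) is an error, not a curve.

Two null models generate the envelope:

* `bm_sim` (default): a Brownian-motion rate is estimated from the
  observed states by maximum likelihood (GLS root state, phylogenetic
  covariance from shared path lengths) and `n_sim` continuous tip data
  sets are simulated under it. This is the convention of the DTT
  literature and treats the integer codes as a discretized continuous
  trait.
* `tip_shuffle`: the observed states are permuted across tips, holding
  the category composition fixed and destroying only the phylogenetic
  arrangement.

The envelope is the pointwise 2.5%/97.5% quantile band (configurable) over
`n_sim = 1000` replicates by default, matching the randomization depth of
the original analysis. Classification follows the rule the analysis
states: observed above the upper quantile is reported `conservatism`,
below the lower quantile `overdispersion`, otherwise `ns`; the MDI-style
summary is the mean of observed minus the pointwise null median. Note that
this rule is a *reporting convention inherited from the study being
reproduced*: in the wider DTT literature low late-time disparity (curve
below the null) is what is usually described as conservatism, so the
labels should be read as "above/below the null", not as settled biological
interpretation. The package computes the curve and envelope identically
under either reading.

## The four rate models

All four models are ER chains whose rate varies with relative time
$t$ (root 0, present 1); each is implemented as a branch-length transform,
so one pruning likelihood serves all of them. A branch spanning
$[t_0, t_1]$ receives effective length $\int_{t_0}^{t_1} r(t)\,dt / q$:

| model | rate $r(t)$ | free parameters | transform |
|---|---|---|---|
| null | $q$ | $q$ | identity |
| delta | depth transform | $q$, $\delta > 0$ | node depths $d \mapsto d^\delta$ |
| linear | $q + s\,t$ | $q$, $s$ | $(t_1 - t_0) + \tfrac{s}{q}\,\tfrac{t_1^2 - t_0^2}{2}$ |
| two-rate | $q$ before $B$, $E$ after | $q$, $B \in [0,1]$, $E > 0$ | split exactly at $B$ |

Identity points ($\delta = 1$, $s = 0$, $E = q$) reproduce the null
likelihood exactly; the test suite asserts this to $10^{-8}$. The delta
identity is taken at $\delta = 1$, the standard parameterization of the
depth-power transform. The linear model enforces $r(t) \ge 10^{-8}$ over
$[0, 1]$ inside the optimizer, keeping rates valid without a hard
reparameterization. The two-rate second rate $E$ is an absolute rate, not
a multiplier of $q$ — the literal reading of how the model is usually
tabulated.

The likelihood is Felsenstein pruning with per-node rescaling, a uniform
root prior (the ER stationary distribution, and the only root treatment
that is self-consistent for a symmetric chain; FitzJohn conditional
weighting is available via `fit_opts(root_prior = "fitzjohn")`), support
for polytomies and for explicitly ambiguous (`NA`) tips. The ER closed
form $P(t) = e^{-kqt} I + (1 - e^{-kqt}) J/k$ reduces each matrix-vector
product to one exponential; the inner loop is compiled (Rcpp). Impossible
data (e.g. $q = 0$ with unequal tip states) yield $-\infty$, which the
optimizer sees as a large finite sentinel so trajectories never propagate
infinities.

## Fitting and model selection

Positive parameters are optimized on the log scale with box constraints
($q, E \in [10^{-4}, 10^3]$ per unit relative time, $\delta \in
[10^{-2}, 10^2]$) and 5 seeded random multi-starts; the first start for
every non-null model is the null maximum-likelihood rate, which guarantees
the nesting inequality $\log L_{\text{model}} \ge \log L_{\text{null}}$
numerically.

The breakpoint likelihood is only piecewise smooth in $B$, so the two-rate
model is profiled over a grid of 101 points on $[0, 1]$, warm-starting
$(q, E)$ along the grid, followed by a joint local refinement of
$(q, B, E)$ within one grid step of the best point. Two structural traps
required explicit handling: the surface contains the flat ridge $q = E$
(the null model at every $B$) and a broad saturated-rate basin, either of
which can stall a purely warm-started chain; every grid point therefore
also tries two rate-contrast anchors (slow-then-fast and fast-then-slow at
0.1 and 10 per unit time). A breakpoint estimate within half a grid step
of 0 or 1 is flagged `B_at_boundary` in the diagnostics, because there
$q$ or $E$ ceases to be identified.

AIC defaults to the reduced counting convention — only parameters beyond
the shared baseline rate are charged (null 0, delta 1, linear 1, two-rate
2), so the null model's AIC equals $-2\log L$ exactly. This matches how
the comparison this package reproduces was tabulated; it shifts every AIC
by the same 2 units relative to the standard all-parameters convention and
therefore never changes the ranking, only the printed values.
`fit_opts(aic_convention = "standard")` switches. `model_table()` sorts by
AIC, reports $\Delta$AIC, and flags when the runner-up is within 2 units —
the conventional threshold below which the simpler model cannot be
rejected.

## Trees: consensus and dating

**Consensus.** Rooted majority rule: a clade is kept iff its frequency
across the input trees is strictly above the threshold (default 0.5, so
exact 50% ties are dropped — a deterministic rule with no arbitrary
tie-break). Each kept clade's branch length is the arithmetic mean of its
subtending edge length over *the trees that contain that clade* — the
simplest reading of "average branch lengths" that is well defined for
clades absent from some trees. The output is generally non-binary, which
is why the pruning code accepts polytomies.

**Dating.** Branch lengths are converted to node ages by minimizing

$$\sum_e (b_e - r_e t_e)^2 \;+\; \lambda \sum_{(e,f)\ \text{adjacent}} (r_e - r_f)^2,$$

a Gaussian penalized fit in which $b_e$ is the observed length, $t_e$ the
implied duration, $r_e$ a per-branch rate, and adjacency links each edge
to its parent edge. For fixed ages the rates are the solution of a small
symmetric positive-definite linear system and are profiled out exactly;
the outer optimization runs over internal node ages parameterized as
fractions of the interval between the parent's age and the present, so the
age ordering holds by construction and the output is ultrametric by
construction (tips at exactly `root_age`). The smoothing weight defaults
to $\lambda = 1$ with no cross-validation — the original analysis states
no value, so the default is an explicit substitute exposed in the
configuration, not an inference of intent. `root_age` defaults to 1 so
downstream times are already relative. Initial ages come from a
path-proportional heuristic ($a_v = d_v / (d_v + h_v)$ with $d$ the depth
from the root and $h$ the mean remaining distance to descendant tips),
clamped away from the interval ends. Rates are not constrained positive:
the Gaussian data term is an approximation, and on inputs with strongly
non-clocklike lengths a locally negative profiled rate is possible; the
objective value is attached to the result for inspection.

## Synthetic data: what it emulates, what it does not

The generators define the conditions under which the package is tested:

* `simulate_yule(n, seed)`: pure-birth trees rescaled to unit depth —
  the simplest ultrametric tree model, standing in for a posterior sample
  of dated trees. Real bird phylogenies are neither pure-birth nor
  unit-depth, but every downstream computation is scale-free in relative
  time.
* `simulate_mk(tree, spec, seed)`: the exact forward model of the fitted
  likelihood (root uniform, ER transitions on transformed branch
  lengths) — verified against exhaustive pattern probabilities in the
  test suite.
* `simulate_bm(tree, rate, seed)`: Brownian tip values for the DTT null.
* `make_fixture_dataset(seed)`: 48 pseudo-species (`Genus_sp01` …)
  carrying the real category composition (EN 1, VU 14, NT 9, LC 24) in
  seeded random order on a seeded Yule tree. The pseudo-names are
  deliberate: attaching the real binomials to a simulated topology would
  imply phylogenetic placements nobody estimated. The verbatim species
  table ships separately (`risk_table_fixture()`) for ingestion tests.

Because the fixture assigns categories at random, it carries *no*
phylogenetic signal by construction. Tests passing on it demonstrate the
machinery (coding, matching, curve construction, fitting, selection), not
any biological conclusion; on such data the fitted rate models correctly
run to degenerate corners (saturated or frozen rates) because that is
where the likelihood of signal-free categorical data lives.

## Problem sizes and runtime choices

The test suite's simulation experiments use sizes chosen to balance
statistical resolution against a comfortable default run: constant-rate
recovery at 200 tips x 50 replicates, breakpoint recovery at 300 tips x 30
replicates (grid of 51 breakpoints during recovery, 101 by default),
envelope calibration at 64 tips x 20 replicates with 200-replicate nulls,
exhaustive-enumeration oracles on trees with at most 5 internal nodes, and
1000-replicate nulls wherever the original randomization depth is being
mirrored. The whole suite runs in about a minute and a half on one core.

## Known limitations

* **The breakpoint time is weakly identified on Yule trees.** Lineages
  accumulate exponentially toward the present, so little branch length
  exists deep in the tree and candidate breakpoints over a wide deep
  interval change the likelihood by less than the noise scale. The
  package's own recovery experiment shows the consequence: with a true
  breakpoint at relative time 0.5 and a fourfold rate increase, the
  estimated breakpoint concentrates near the late boundary (median
  ≈ 0.86 at 300 tips, essentially unchanged at 2000 tips), with the
  boundary fit beating the truth by only ~1–3 log-units — the two
  processes are nearly observationally equivalent. The `B_at_boundary`
  diagnostic exists precisely because a boundary-pinned breakpoint should
  be read as "a rate shift sometime, location unknown", not as an
  estimate. This mirrors the original analysis's own boundary-adjacent
  breakpoint being discarded as unrealistic.
* **The rate scale is relative.** All rates are per unit of relative time
  on a unit-depth tree; comparing them to rates fitted on an absolute
  timescale requires dividing by the root age.
* **The BM null treats integer codes as continuous.** That is the only
  way the standard DTT machinery applies to coded categories, and it is
  shared with the analysis being reproduced; the `tip_shuffle` null is the
  distribution-free alternative.
* **Dating assumes the Gaussian approximation.** The penalized objective
  is a least-squares surrogate for a rate likelihood; it is fast,
  deterministic and adequate for averaged branch lengths, but it is not a
  substitute for calibrated Bayesian dating when absolute ages matter.
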