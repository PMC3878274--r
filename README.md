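# riskevo

Phylogenetic comparative analysis of extinction risk. `riskevo` asks two
questions about IUCN Red List categories placed on a dated species
phylogeny — here, the 48 bird species endemic to mainland China:

1. **Is extinction risk phylogenetically structured?** Categories are coded
   as ordinal states (EN = 1, VU = 2, NT = 3, LC = 4) and summarized as a
   *disparity-through-time* (DTT) curve: at each internal-node time *t* of
   the tree, the mean pairwise squared difference of the states within each
   lineage crossing *t*, averaged across lineages and standardized by the
   whole-clade disparity. The curve starts at 1 at the root; where it lies
   relative to a randomization null (pointwise 95% envelope from
   Brownian-motion simulations or tip shuffles) is reported per time point,
   together with an MDI-style summary (mean observed − null difference).

2. **Does the rate of risk evolution change through time?** The states are
   modeled as a 4-state equal-rates (ER) Markov chain,
   P<sub>ii</sub>(t) = 1/k + (1−1/k)e<sup>−kqt</sup>,
   P<sub>ij</sub>(t) = (1−e<sup>−kqt</sup>)/k, with four variants of the
   rate through relative time (root = 0, present = 1): **null** (constant
   *q*), **delta** (Pagel's δ power transform of node depths), **linear**
   (*q* + *s·t*), and **two-rate** (*q* before a breakpoint *B*, rate *E*
   after). Likelihoods come from Felsenstein pruning (C-accelerated,
   polytomy-safe); models are compared by AIC. The default AIC counts only
   parameters beyond the shared baseline rate, so AIC<sub>null</sub> =
   −2 logL; a standard all-parameters convention is available.

Supporting machinery: Newick/Nexus I/O, majority-rule consensus with
averaged branch lengths over a tree sample, penalized-likelihood
ultrametricization (Gaussian data term with a smoothness penalty λ on
parent–child rate changes), and seeded simulators (Yule trees, ER states
under any of the four models, Brownian tip values) used for the nulls and
for testing.

## Worked example

The 48-species table ships with the package. A dated phylogeny for these
species is journal supplementary material and is not redistributed here, so
the example places the species on a seeded unit-depth Yule tree (a labelled
stand-in, not a real phylogeny):

```r
library(riskevo)

records <- read_risk_table(risk_table_fixture())
coded   <- code_categories(records)
coded
#> coded_states: 48 species coded ( EN 1, VU 14, NT 9, LC 24 ), 0 excluded

tree <- simulate_yule(48, seed = 1)
tree$tip.label <- gsub(" ", "_", records$species)
matched <- match_to_tree(coded, tree)

curve <- dtt_null(tree, matched, n_sim = 1000, seed = 42)
rep <- conservatism_report(curve)
round(rep$mdi, 3)
#> 0.386
table(rep$table$call)
#> conservatism           ns
#>           43            4
```

The observed relative disparity sits above the Brownian null at 43 of 47
time points: risk states within subclades are more variable, relative to
their own clade disparity, than a Brownian process on this tree would
produce — on real category data this curve is the analysis's Figure-style
product; on the random stand-in tree it mostly reflects the absence of true
phylogenetic placement.

Model fitting and selection, shown on states simulated under a known
constant rate (q = 0.5) so the answer is checkable:

```r
st <- simulate_mk(tree, model_spec("null", q = 0.5), seed = 7)
fits <- lapply(c("null", "delta", "linear", "two_rate"),
               function(k) fit_model(tree, st, k, fit_opts(seed = 1)))
model_table(fits)
#>      model   logL      q            params   AIC delta_AIC  best
#> 1     null -46.07 0.5341                 - 92.14     0.000  TRUE
#> 2   linear -45.87 0.1683          s=0.4471 93.74     1.602 FALSE
#> 3    delta -45.94 0.3792       delta=1.618 93.87     1.734 FALSE
#> 4 two_rate -45.27 0.3607 B=0.9846, E=2.558 94.54     2.402 FALSE
```

The constant-rate model is preferred and recovers the generating rate; the
richer models gain too little likelihood to justify their extra parameters.

## The analysis workflow

`analysis/` holds the numbered drivers that run the whole study pipeline
and write their tables under `results/`:

| script | does | writes |
|---|---|---|
| `01_ingest_and_code.R` | reads the species table, codes categories, logs exclusions | `states.tsv`, `exclusions.tsv` |
| `02_consensus_and_dating.R` | simulates a jittered tree sample, majority-rule consensus with averaged branch lengths, penalized-likelihood dating | `tree_sample.nwk`, `dated_tree.nwk` |
| `03_disparity_through_time.R` | DTT with a 1000-replicate Brownian null and conservatism calls | `dtt.tsv`, `dtt.pdf` |
| `04_model_fits.R` | ML fits of the four rate models, AIC table, published-AIC reconstruction | `model_table.tsv`, `published_aic.tsv` |

`run_pipeline()` performs the same chain (consensus → dating → coding →
DTT → fits) as a single call on arbitrary input files.

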