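# phylocausal

Phylogenetic causal analysis of binary traits: signal, path analysis, and
spatiophylogenetic mixed models.

Languages (like species) inherit their features from their ancestors, so
cross-linguistic correlations cannot be read causally off raw counts —
related languages are not independent data points (Galton's problem). This
package implements, as a reusable and fully tested pipeline, the three-stage
analysis used to ask how the strategies for marking "who does what to whom"
— morphological **case** on core arguments, **verb-final** order, and
**flexible** (non-fixed) order of core arguments — cause one another over
time on a global language phylogeny. Every stage works on any rooted tree
with binary tip data.

1. **Phylogenetic signal (D metric).** For a binary trait, the sum of
   sister-clade differences Σd is rescaled between two simulated reference
   points on the same tree:
   `D = (d_obs − mean_Brownian) / (mean_random − mean_Brownian)`,
   so D ≈ 1 for a phylogenetically random trait and D ≈ 0 for a trait
   evolving as a thresholded Brownian liability. One-sided Monte-Carlo tail
   probabilities test departure from each pole.
2. **Phylogenetic path analysis.** Competing causal structures are DAGs over
   the three traits (a built-in set of 12 plus the null). Each DAG's
   d-separation basis set is tested with phylogenetic regressions (logistic
   with an estimated correlation-decay parameter, or Gaussian PGLS); each
   model is scored with Fisher's `C = −2 Σ ln pᵢ` (χ², 2k df) and the
   small-sample criterion `CICc = C + 2qn/(n − 1 − q)`, `q = |V| + |E|`.
   Supported models (ΔCICc ≤ 2, claim p ≥ 0.05) have their standardized path
   coefficients conditionally averaged by CICc weight.
3. **Bayesian logistic mixed models.** `logit P(y=1) = Xβ + u + v` with
   `u ~ N(0, σ²ₚ C_phylo)` and `v ~ N(0, σ²ₛ C_spatial)`; the spatial kernel
   is Matérn (κ = 1, φ = 1.25) over great-circle distances. A purpose-built
   MCMC sampler (elliptical slice sampling plus interweaving; validated
   against exact quadrature) yields posteriors; random-effect structures are
   compared by 10-fold cross-validated expected log predictive density, and
   the supported path models are refit path-by-path with credible intervals.

A synthetic-data module (Yule trees, DAG-coupled threshold liabilities,
Matérn spatial fields, raw-feature emission) makes the whole pipeline
runnable and testable with no external downloads.

## Worked example

Generate data under the mediation chain *verb-final → case → flexible*
(structural effect 1.5 on the liability scale, 500 tips), then run the first
two stages:

```r
library(phylocausal)

ds   <- simulate_dataset(builtin_scenario("model_c", n_tips = 500, seed = 5))
corr <- phylo_correlation_matrix(ds$tree)

d_statistic(ds$tree, ds$traits$case, n_perm = 1000, n_sim = 1000, seed = 1)
#> D statistic of phylogenetic signal (binary trait, 500 tips)
#>   D = -0.000  (sum of sister differences = 80.34)
#>   random pole mean = 193.35, Brownian pole mean = 80.39
#>   P(random | data)   : p = 0.000  [departure from D = 1]
#>   P(Brownian | data) : p = 0.537  [departure from D = 0]
```

The trait tracks the tree almost perfectly (D ≈ 0: indistinguishable from
Brownian threshold evolution; decisively different from random, p < 0.001) —
expected, since `case` was generated on the tree.

```r
pp <- fit_path_models(ds$traits[analysis_traits()], corr)
head(tidy(pp), 5)
#>   model_id  CICc delta_CICc relative_likelihood weight     k     q     C model_p
#> 1 c         12.2      0                   1      0.335     1     5  2.06   0.358
#> 2 b         12.2      0.018               0.991  0.332     1     5  2.08   0.354
#> 3 d         12.2      0.018               0.991  0.332     1     5  2.08   0.354
#> 4 a         69.1     57.0                 0      0         1     5 59.0    0
#> 5 e         77.1     65.0                 0      0         1     5 67.0    0
```

The generating model `c` and its two Markov-equivalent relabelings (`b`,
`d`) — which imply the *same* conditional independence, tested in mirrored
regression directions — are the only supported models; every other topology
is decisively rejected (model p < 0.05, ΔCICc ≫ 2). Conditional averaging of
the supported set returns standardized path coefficients with 95% bounds:

```r
average_top_models(pp)[1:5]
#>   from       to         estimate lower95 upper95
#> 1 verb_final case           1.06    0.85    1.27
#> 2 case       flexible       1.38    1.12    1.65
#> 3 case       verb_final     1.69    1.4     1.99
#> 4 flexible   case           0.88    0.71    1.06
```

All four averaged paths are positive with bounds excluding zero — the
simulated reinforcement between case and the word-order traits is recovered.
`run_pipeline()` chains these stages (plus cross-tabulations, K-fold
random-effect comparison and mixed-model refits) from a single YAML or list
config and writes CSV/JSON reports with a checksum manifest; see the methods
vignette (`vignettes/phylocausal-methods.Rmd`) for the models, priors,
samplers and design decisions.

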