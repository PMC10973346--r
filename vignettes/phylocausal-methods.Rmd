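---
title: "Methods: phylogenetic causal analysis of binary traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic causal analysis of binary traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phylocausal` implements a three-stage comparative analysis of binary traits
observed at the tips of a phylogeny, motivated by the cross-linguistic
question of how languages mark "who does what to whom": morphological case on
core arguments, verb-final constituent order, and flexible (non-fixed) order
of core arguments. Because languages inherit grammar from their ancestors,
observations are not independent (Galton's problem), and every stage controls
for the phylogeny explicitly. All three stages run equally well on any rooted
tree with binary tip data — nothing in the machinery is specific to language.

## Stage 1 — phylogenetic signal: the D metric

For a binary trait the package measures signal with the D metric: the
observed sum of sister-clade differences, `sum(|v_left - v_right|)` over
internal nodes, where node values are branch-length-weighted averages of the
two children (weights `1/branch`), computed in one post-order pass. Raw sums
are not comparable across trees or prevalences, so the observed sum is
rescaled between the means of two simulated reference distributions computed
on the same tree with the same prevalence:

* **random pole** (D = 1): tip labels permuted uniformly;
* **Brownian pole** (D = 0): a latent liability evolves by Brownian motion
  along the tree (variance proportional to branch length) and is thresholded
  at the empirical quantile so that the simulated prevalence matches the
  observed count exactly.

`D = (d_obs - mean_brownian) / (mean_random - mean_brownian)`. Two one-sided
tail probabilities are reported: `p_random`, the proportion of permutation
sums at or below the observed sum (departure from the random pole), and
`p_brownian`, the proportion of Brownian sums at or above it (departure from
the Brownian pole). Both nulls default to 1000 draws; every simulation takes
an explicit seed and no global random state is used. Polytomies are resolved
to zero-length binary nodes deterministically (left-to-right) because the
statistic is built from sister pairs; zero-length branches are floored at
`1e-8` of the maximum branch before inverse weighting.

## Stage 2 — phylogenetic path analysis

Competing causal hypotheses are expressed as DAGs over the three traits. The
testable content of a DAG is its d-separation basis set: one conditional
independence claim per non-adjacent vertex pair, conditioning on the union of
the two vertices' parents. Claims are directional in testing: the designated
response is the member of the pair that is not a causal ancestor of the
other, and when neither is an ancestor the lexicographically last vertex is
regressed. This tie-break is what lets two Markov-equivalent models receive
different C statistics — their claim is the same conditional independence
tested in opposite regression directions — and it reproduces the pattern in
the published comparison where the two runner-up models share an identical C.

Each claim is tested by regressing the response on the claim variable plus
its conditioning set with one of two engines:

* `"logistic"` (default): logistic regression whose working residuals are
  phylogenetically correlated, `corr(i, j) = exp(-alpha * d_ij)` with `d_ij`
  the patristic distance on the unit-height tree. The decay `alpha` is
  profiled by a Gaussian pseudo-likelihood of the Pearson residuals within
  fixed bounds `[1e-4/h, 50/h]`; the upper bound is treated as the exact
  independence limit, where the estimator coincides with ordinary logistic
  maximum likelihood. If the unpenalized fit diverges (separation), a ridge
  equivalent to a Normal(0, 2) prior is applied and flagged. Wald z
  p-values.
* `"gls"`: Gaussian PGLS on the 0/1 response under the fixed Brownian
  correlation matrix of the tree (Cholesky whitening, t-based p-values with
  `n - rank(X)` degrees of freedom), for sensitivity analysis.

The data are binary, so the logistic engine is the default; the GLS engine
replicates the Gaussian description of the method and gives a robustness
check. Matrix solves use Cholesky factorizations with diagonal jitter
starting at `1e-10` and escalating tenfold to at most `1e-6`.

A model with k claims is summarized by Fisher's C, `-2 * sum(log p_i)`
(p-values floored at `1e-300` so that decisive rejections keep C finite),
its chi-squared upper tail with 2k degrees of freedom, and the small-sample
information criterion `CICc = C + 2 q n / (n - 1 - q)` with `q = |V| + |E|`
parameters. Models are ranked by CICc; `delta`, relative likelihoods
`exp(-delta/2)` and weights normalized over the full fitted set (including
the null) follow the usual information-theoretic recipe. Supported models
are those within `delta <= 2` of the best with claim p-values at or above
0.05; their standardized path coefficients (raw coefficient times predictor
standard deviation, binary predictors included) are conditionally averaged:
each path only over the models that contain it, with weights renormalized in
that subset, and 95% bounds averaged with the same weights. Averaging the
bounds is an explicit simplification — the aggregation of interval endpoints
is not uniquely defined for weighted model mixtures — and full-average mode
is available behind a flag.

### The built-in 12-model set

Four single-edge models encode the published diachronic scenarios
(verb_final -> case and case -> flexible, plus both reversals). The
published worked rows pin down three of the eight two-edge models: the fork
out of case and the two mediation chains through case. The remaining letters
are not recoverable from the source text, so the set is completed by a
fixed, documented choice: all six two-edge mediation chains among the three
variables, the fork out of case, and the collider into case (both word-order
features feeding case — the "word order causes case" scenario). Forks and
colliders centred on the word-order pair are omitted. Model letters are
therefore stable package identifiers; topologies, not letters, are the unit
of interpretation, and `flag_equivalent_models()` marks Markov-equivalent
members.

## Stage 3 — Bayesian spatiophylogenetic logistic mixed models

To ask whether phylogeny alone explains the trait distributions, or spatial
proximity is needed, the package fits
`logit P(y = 1) = X beta + u + v`, `u ~ N(0, sigma_p^2 C_phylo)`,
`v ~ N(0, sigma_s^2 C_spatial)`, with either or both terms present.
`C_phylo` is the Brownian correlation of the unit-height tree; `C_spatial`
is a Matern kernel (`kappa = 1`, range `phi = 1.25`) over great-circle
distances, both normalized to unit diagonal so the two scales are
comparable. Distances are divided by 200 km per Matern unit by default: with
`phi = 1.25, kappa = 1` this puts high correlation within a few hundred
kilometres and drives it below 0.05 near 1000 km, the stated qualitative
behaviour of the spatial effect; the scaling is a configuration knob because
the original unit convention is not recoverable. Priors are weakly
informative — Normal(0, 2.5) on coefficients, half-Student-t(3, 0, 2.5) on
scales — and configurable.

The posterior is sampled with a custom MCMC cycle designed around the
Gaussian structure of the model: (i) elliptical slice sampling of the
whitened block (coefficients and latent fields jointly — interpolation along
the ellipse is linear, so each angle evaluation costs O(n)); (ii) slice
sampling of each log scale in the non-centered conditional; (iii) an
ancillarity-sufficiency interweaving step that redraws the scale holding the
*centered* field fixed (an independence inverse-gamma proposal accepted on
the half-t prior ratio alone); and (iv) a likelihood-invariant translation
between the intercept and the field mean. Steps (iii) and (iv) remove the
two strongest posterior couplings of this model family. Several sweeps of
the cycle are run per stored draw (default 3). The sampler was checked
against exact quadrature of the two-tip posterior (whitened-grid
integration); that oracle is part of the test suite. Convergence is
summarized by split-chain R-hat and an initial-positive-sequence effective
sample size per parameter; by default a fit whose diagnostics exceed the
thresholds (R-hat 1.01) raises an error rather than returning silently.

Random-effect structures are compared by K-fold cross-validation (the
conventional K = 10): each refit scores its held-out fold by the expected
log predictive density, integrating the held-out latent effects over their
conditional Gaussian distribution given the training-fold latents per
retained posterior draw. Pairwise elpd differences are reported with
standard errors; models within two standard errors are flagged as
predictively equivalent. Finally, the supported path models can be refit
path-by-path as logistic mixed models with a phylogenetic random effect
only — a single shared structure keeps the refits comparable, and the
spatial term adds little once phylogeny is included — reporting posterior
means and 95% credible intervals and flagging paths whose interval includes
zero.

## Synthetic data: what it emulates and what it does not

The generator produces (a) Yule trees scaled to unit height; (b) binary
traits from threshold liabilities: each trait's liability is the sum of
`beta * z_parent` over its causal parents (`z` the centered binary parent
values) plus a Brownian error with the tree's correlation, thresholded at
the quantile matching the requested prevalence; (c) clustered coordinates
and Matern-correlated spatial fields; and (d) the inverse of the feature
derivation, emitting raw five-feature records whose round-trip through
`derive_features()` is the identity. Scenario defaults are the study
conditions: trait prevalences 0.33 / 0.37 / 0.38 (the sample co-occurrence
percentages imply these), structural effects of 1.5 on the liability scale —
strong but not deterministic coupling — and 500 tips for recovery
experiments. A parentless trait follows exactly the same code path as the
D metric's Brownian null, so the two stages are mutually consistent by
construction. The spatial simulator adds a small independent nugget to the
Matern field before thresholding: thresholding is scale-invariant, so
without the nugget the zero-variance limit would freeze the spatial pattern
instead of degenerating to an exchangeable (i.i.d. Bernoulli) draw.

Because coupling acts through the *binary* parent value, conditioning on a
binary mediator blocks the causal path exactly; real liabilities would leak
dependence through a coarsened mediator. The generator also omits borrowing
and contact (horizontal transmission), non-Yule tree shapes, and any
latent sociolinguistic confounders. Passing tests therefore demonstrate the
statistical machinery under its own assumptions, not the robustness of the
method to the full messiness of real cross-linguistic data. A consequence
worth stating plainly: under a generated mediation chain, the generating
model and its Markov-equivalent relabelings are *all* exactly consistent
with the data, so which member of the equivalence class ranks first is
decided by the finite-sample asymmetry of two mirrored regressions, not by
identifiable causal content.

## Numerical and design choices

* Trees are rescaled to unit height before correlation matrices are built,
  so decay and scale parameters are comparable across trees.
* Listwise deletion over the three derived traits precedes any analysis
  (one shared sample for the whole pipeline); pruning order is data
  completeness first, then tree intersection.
* A language coded verb-final alongside another unmarked order counts as
  not exclusively verb-final (0) with a warning; an option turns it to NA.
* Exact-count thresholding (ties broken by liability rank) keeps simulated
  prevalences deterministic given the seed.
* Every stochastic routine takes a seed; sub-streams are derived by hashing
  the seed with a role label, so adding a stage never shifts another
  stage's draws.
* Reports round statistics to two decimals and percentages to integers.
* Problem sizes used by the validation suite — 300-tip trees with 1000-draw
  nulls for signal calibration, 100 runs at 500 tips for structure
  recovery, 20 replicates at 300 tips for posterior coverage — were chosen
  as the smallest sizes at which the corresponding population quantities
  are estimated with comfortable Monte-Carlo margins.

## Known limitations

* The logistic engine is a quasi-likelihood estimator; its p-values are
  asymptotic and its decay parameter is profiled, not integrated over.
* Conditional averaging of interval bounds understates between-model
  variance relative to a full mixture interval.
* K-fold elpd uses thinned posterior draws (up to 200 per chain) for the
  conditional integration; very small folds inherit that Monte-Carlo noise.
* The spatial model treats languages as points; ranges, polygons and
  directional contact are out of scope.
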