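---
title: "Methods: modular clustering and response-surface modeling of multivariate DOE responses"
author: "fermrsm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modular clustering and response-surface modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermrsm)
```

## The problem

Wine fermentation experiments that vary several production factors at once —
here initial sugar content (S), yeast assimilable nitrogen (N), fermentation
temperature (T) and the co-inoculation level of a non-Saccharomyces adjunct
yeast (I) — produce many responses per run: kinetic summaries such as the
time to dryness (R100) and the maximum fermentation rate (MFR), the primary
fermentation products (ethanol, glycerol, acetic acid) and a panel of
volatile aroma compounds. These responses are neither independent nor fully
redundant: they come in functional modules. Modeling each response
univariately ignores that structure and multiplies the number of fitted
surfaces; modeling all responses jointly with one latent model ignores the
modularity. `fermrsm` implements a middle road in three stages:

1. **Autoscale and summarize.** Each response column is z-transformed to
   zero mean and unit sample standard deviation so that all later analysis
   sees only the correlation structure. Numeric per-factor-level summaries
   and the full pairwise correlation matrix replace plot-only exploration.
2. **Find the modules.** The response *variables* are clustered by
   agglomerative hierarchical clustering under the correlation distance
   `d(j, l) = 1 - |r_jl|`, and the dendrogram is cut at a user-chosen number
   of clusters `k`.
3. **Model each module once.** Each cluster is summarized by the first
   principal component of its member columns (the PC1 surrogate). The PC1
   scores are regressed on the design factors by forward stepwise selection
   over the full second-order candidate set (main effects, pairwise
   interactions, quadratics), with entry and removal decided by partial
   F-tests. Member responses are recovered from the fitted surrogate by the
   outer product with the PC1 loading vector, followed by inversion of the
   autoscaling.

## The experimental design

The supported design is the single-block face-centered central composite
design (CCD): `2^k` factorial corners at coded ±1, `2k` axial points with a
single coordinate at ±1, and replicated center points. With four factors and
seven center replicates this gives the 31-run plan the package emulates.
Only the face-centered star distance (alpha = 1) is implemented: the factor
specification defines exactly three physical levels per factor, so any other
star distance would require levels the specification cannot decode. Coded
levels are stored as exact integers {−1, 0, +1}; physical units are derived
on demand through the linear map `mid + coded * (high - mid)`, which is why
`factor_spec()` requires `mid = (low + high) / 2`. Run-order randomization
is a seeded uniform permutation; the mechanism is our choice, since
randomized execution is usually reported without the generator.

```{r design}
design <- generate_ccd(n_center = 7, seed = 1)
design
validate_design(design)
```

## The synthetic-data generator

The per-run response values of the motivating study live in an appendix that
is not reproduced alongside the summary tables, so the generator is the
package's source of verifiable data. It runs the analysis's reconstruction
step in reverse. Each of five modules (sizes 1/2/7/3/5, covering 18
responses) has a latent polynomial score
`s_c(x) = sum_t beta_ct g_t(x)` over the coded factors, where each `g_t` is
a main effect, a pairwise product or a square. Member `j` of module `c`
takes the value

```
y_ij = mu_j + lambda_j * (p_cj * s_c(x_i) + eps_ij),   eps_ij ~ N(0, sigma_c^2)
```

with `p_c` the unit loading vector of the module. The default module
definitions (`default_truth()`) transcribe the reported cluster
compositions, PC1 loadings and standardized effect sizes of the reference
study — e.g. the singleton ethyl-acetate module driven by inoculum
(`I = 0.7592`, `N:I = -0.2088`), or the anti-correlated kinetics pair
R100/MFR with loadings ∓0.7071. Printed 4-decimal loading vectors are
renormalized to unit norm; the rescaling factor is recorded in each module's
provenance field.

Defaults and why:

* `noise_sd = 0.05` on the standardized scale. The study gives no noise
  model; replicated center points in real fermentations scatter, so a small
  nonzero residual is more realistic than none, and 5% of the standardized
  member scale keeps the modules clearly separated without making recovery
  trivial.
* Noise is Gaussian, homoscedastic within a module and independent across
  runs and members. It enters *before* the per-member scale `lambda_j`, so
  autoscaling the simulated data approximately recovers the standardized
  generating model.
* `mu_j = 0`, `lambda_j = 1` by default: the pipeline autoscales anyway, so
  physical-unit decoration is cosmetic.

What the generator does **not** emulate: fermentation kinetics (no ODEs or
population dynamics), heteroscedastic or non-Gaussian measurement error,
missing values, and any dependence of the noise on the factor levels.
Passing the recovery tests therefore shows that the pipeline identifies
modular polynomial structure under well-behaved noise — not that real
fermentation data satisfy those assumptions.

## Stage 2 choices

**Distance.** The unsigned correlation distance `1 - |r|` is the default
because functional modules can contain anti-correlated members: a
fermentation that finishes faster has a shorter R100 and a larger MFR, and
the reported kinetics cluster indeed carries opposite-sign loadings. The
signed form `1 - r` would tear such modules apart; it remains available via
`distance = "signed"` for comparison.

**Linkage.** Average linkage (UPGMA), the conventional choice for variable
clustering with correlation distances; complete and single linkage are
selectable. The underlying agglomeration is `stats::hclust`, cross-checked
in the test suite against a naive full-re-scan oracle on small problems.

**Number of clusters.** `k` is a required input (default 5 in the pipeline
configuration, matching the five reported modules). No automatic cut-height
heuristic is applied: with 18 variables and 31 runs, automatic rules are
fragile, and the choice of `k` is a scientific statement about the system.

**Sign convention.** Every principal component is oriented so that the
variable with the largest absolute loading has a positive loading (first
such variable on ties). This makes loadings, scores and downstream
regression coefficients deterministic across linear-algebra backends; only
signs, never fits or p-values, depend on it.

## Stage 3: the stepwise surrogate models

For each cluster, PC1 of the member columns is the response. The candidate
terms for `k` factors are the `k` mains, `k(k-1)/2` interactions and `k`
quadratics — 14 terms for four factors — in a fixed canonical order. All
term columns are standardized (centered, unit sample sd) before fitting, so
coefficients are reported on the standardized predictor scale. In a
face-centered design the quadratic columns take raw values in {0, 1} and are
correlated with each other and with the intercept; they are standardized
like any other term and no orthogonalization is applied — the partial-F
machinery handles correlated candidates.

The greedy loop: at each iteration, for every excluded term compute

```
F = (RSS_reduced - RSS_full) / (RSS_full / (n - p_full)),  df = (1, n - p_full)
```

for adding that term alone; admit the smallest-p term if `p < alpha_enter`
(ties broken toward the earlier canonical label). Then re-test every
included term and drop the largest-p one if `p > alpha_remove`. Stop when
neither scan changes the model. For a single added term this F equals the
squared t-statistic of the term's coefficient in the augmented model — an
identity the test suite checks to 1e-8 against `lm()`.

Numerical and policy choices:

* `alpha_enter = alpha_remove = 0.05`: a single reference significance level
  for both directions, as in the motivating workflow.
* No effect heredity: an interaction or quadratic may enter without its
  parent mains. The reported models require this (e.g. a model of `{N, S^2}`
  with no S main effect).
* Degrees-of-freedom guard: an addition that would leave fewer than 2
  residual degrees of freedom, or a rank-deficient fit, is ineligible that
  iteration and recorded in the selection trace.
* Perfect-fit guard: once the residual sum of squares falls below
  `1e-10 × TSS` the entry scan stops — on noiseless data the partial-F ratio
  would otherwise degenerate to 0/0.
* An iteration cap (50) breaks pathological add/drop cycles; with equal
  entry and removal thresholds none have been observed.
* The PC1 scores are used as-is (they are centered by construction but not
  rescaled to unit variance). This affects coefficient magnitudes, not
  selection or p-values; reported coefficients are therefore on the scale of
  the cluster's PC1.

Reconstruction maps fitted surrogate scores back to member responses:
`z_hat = t_hat ⊗ p`, then `y_hat = mean + sd * z_hat` per member using the
scaling stored by `autoscale()`.

```{r stage3}
res <- run_pipeline(pipeline_config(noise_sd = 0.05, seed = 42))
res$ledger[[4]]$terms
```

## Determinism and seeds

A pipeline run is a pure function of its configuration. The global `seed`
fans out to per-stage child seeds through a fixed rule (the i-th draw of a
seeded integer stream), so adding a stage never changes earlier stages'
randomness. Seeded helpers restore the caller's RNG state. Ledger JSON is
written with 17 significant digits so doubles survive the round trip
bit-exactly; analysis artifacts contain no timestamps, making repeated runs
byte-identical (the plain-text log carries the wall clock).

## Problem sizes used in validation

The test suite validates the workflow at the scale of the emulated study:
31-run designs with 18 responses. Module-recovery checks use 100 simulated
datasets at the default noise level; effect-recovery checks use 200
replicates of all five cluster models; stepwise-path equivalence against a
brute-force greedy oracle uses dozens of small instances with at most 7
candidate terms, where exhaustive refitting is cheap; the partial-F identity
is checked on 1000 random instances. These sizes were chosen to make the
Monte-Carlo rates stable at the percent level.

## Known limitations

* Only face-centered CCDs; no rotatable or orthogonal variants, fractional
  factorials, blocking or D-optimal augmentation.
* No lack-of-fit testing against center-point pure error, no
  cross-validation of R², and no optimization/desirability analysis over the
  fitted surfaces.
* Outliers are never dropped automatically; high-leverage runs are a matter
  for the analyst's judgment on the score plots.
* Stepwise selection with correlated candidates inherits the usual caveats:
  at the 0.05 threshold, occasional spurious terms enter (at single-digit
  percent rates per term in the recovery experiments), and selected sets
  should be read as "factors with strong evidence", not as a unique true
  model.
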