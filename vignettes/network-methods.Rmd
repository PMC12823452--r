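---
title: "Estimating bridge networks from weighted ordinal surveys: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bridge networks from weighted ordinal surveys: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
```

bridgenet estimates how functional-disability domains and mental well-being
interconnect in survey data, using a Gaussian graphical model whose edges
are regularized partial correlations, and asks which nodes *bridge* the
well-being and disability communities. This vignette is the package's
account of the statistical machinery: the model and its assumptions, every
tunable that matters, what the synthetic generator does and does not
emulate, and the numerical choices a reader would otherwise have to dig out
of the source.

## The model and its assumptions

The network view treats the 18 analysis variables — two well-being items,
ten disability domains, six confounders — as nodes of a partial-correlation
network. The estimation chain is:

1. **Weighted available-case correlation.** Each pairwise correlation is a
   weighted Pearson moment over the respondents observed on *both* items,
   with the sampling weights renormalized within that pair
   (`weighted_correlation()`, `missing = "pairwise"`). Listwise deletion is
   available and the two agree exactly on complete data.
2. **Positive-definiteness repair.** Pairwise deletion can make the matrix
   indefinite; `nearest_pd_repair()` projects onto the nearest correlation
   matrix (Higham alternating projections via `Matrix::nearPD`) with an
   eigenvalue floor of 1e-8, and flags whether anything changed.
3. **Graphical lasso with EBIC selection.** `ebic_glasso()` fits the
   L1-penalized precision matrix along a descending penalty path and keeps
   the fit minimizing EBIC at γ = 0.5. Edges are the standardized negative
   precision entries.
4. **Centralities.** Expected influence is a node's signed edge sum; bridge
   expected influence is the signed sum of its edges into the *other* of
   the two bridge communities. Confounder nodes participate in estimation
   (their edges absorb shared sociodemographic variance) but sit outside
   the bridge definition, so their BEI is reported as missing, not zero.

The substantive assumptions are those of any cross-sectional GGM on ordinal
data: an underlying approximately multivariate-Gaussian dependence
structure, symmetric (undirected) relationships, and treating item codes as
interval-scaled. Pearson correlations on 4- and 5-level codes attenuate
latent associations; we return to this below because it matters for how
simulation results should be read.

## Tunable parameters

| Parameter | Default | Where | Why this default |
|---|---|---|---|
| `gamma` | 0.5 | `estimator_config()` | the conventional EBIC setting favouring sparsity |
| `n_lambda`, `lambda_min_ratio` | 100, 0.01 | `estimator_config()` | the dominant psychometric-network path convention: log-spaced from `λ_max` (empty network) down to `λ_max/100` |
| `method` | `"pearson"` | `estimator_config()` | weighted Spearman available; no established weighted-polychoric convention exists, so polychoric is out of scope |
| `missing` | `"pairwise"` | `estimator_config()` | available-case analysis; listwise for sensitivity |
| `n_permutations` | 1000 | `network_compare()` | add-one permutation p-values, so the smallest attainable p is 1/1001 |
| `n_boot` | 5000 | both bootstraps | the study-design default for edge CIs and stability |
| `drop_grid` | 0.05–0.75 by 0.1 | `case_dropping_stability()` | the standard case-dropping grid; CS is the largest grid point with P(r ≥ 0.7) ≥ 0.95 |
| `m`, `n_iterations`, `k` | 10, 10, 5 | `impute_chained()` | ten chained imputations; PMM with five donors keeps imputations inside the observed category support |
| `alpha` | 0.05 | `analysis_config()` | two-tailed throughout |

The case count `n` fed to EBIC is the number of rows with at least one
observed node: survey weights in these designs are normalized to the
sample size, and the `log n` term expects a case count, not a weight sum.

## The synthetic generator

`cfm_spec()`/`simulate_survey()` draw ordinal surveys from a known truth so
that recovery, calibration, power, coverage and stability can all be
checked against ground truth:

* a latent multivariate Gaussian per group with covariance equal to the
  standardized inverse of the group's precision matrix (unit variances, so
  thresholds are marginal quantiles);
* per-node thresholds that put most mass in the lowest code (60/25/10/5%
  across the four disability codes; a flatter five-way split for the
  well-being frequency items), mimicking the right-skew typical of
  difficulty items — the real item marginals are not published, so these
  defaults are plausible rather than calibrated;
* log-normal sampling weights (sdlog 0.5) normalized to mean 1 per group;
* completely-at-random missingness, 9% by default, matching the
  missing-data share such cohorts typically exclude;
* group differences injected by an explicit edge-edit list (by default:
  stronger anxiety bridges for males, stronger depression bridges for
  adolescents), so power experiments are scriptable.

What it does **not** emulate: multistage cluster sampling and stratification
(weights are i.i.d. draws, not design weights), non-random missingness,
item-level sub-questions (it generates domain scores directly), and any
non-Gaussian latent dependence. Tests passing on this generator therefore
validate the estimation machinery, not the measurement model of any real
survey.

A consequence worth stating plainly: Pearson correlations of the
*discretized* codes are attenuated relative to the latent correlations
(roughly 25–35% at these thresholds), so edge weights estimated from
ordinal codes sit systematically below the latent truth. Recovery and
coverage experiments in the test suite are run on the latent scale where
the estimand matches the generator's truth; ordinal-scale runs check
structure recovery, not weight equality.

## Numerical choices

* **Solver.** The graphical lasso is blockwise coordinate descent
  (compiled, warm-started along the path), penalizing off-diagonals only.
  Convergence is declared on the duality gap
  `tr(SK) + λ‖K‖₁,off − p < 1e-6`, which is exact for this
  parameterization; non-convergence is an error carrying λ and the gap,
  never a silent result.
* **Path and ties.** λ descends log-spaced from the saturation bound
  `max|s_ij|` (provably empty network) and EBIC ties break toward the
  larger penalty, i.e. the sparser model.
* **Edges vs numerical zeros.** Entries below 1e-10 in absolute value are
  zeroed; the per-column lasso keeps exact zeros, so this only trims
  round-off.
* **Permutation p-values** use the add-one convention
  `(1 + #{perm ≥ obs}) / (1 + B)`; per-node BEI tests are two-sided on the
  absolute difference, BH-corrected across the twelve bridge nodes.
* **Bootstraps.** Percentile CIs (2.5/97.5%), not BCa — distribution-free
  and matching the field's convention. Resampled respondents keep their
  weights; no per-resample weight renormalization. The case-dropping
  budget is split evenly across the drop grid, and the CS coefficient is
  recomputable from the stored raw correlation draws (they are retained in
  the result object for audit).
* **Imputation pooling.** The m completed tables are pooled by averaging
  their correlation matrices and estimating one network, rather than
  averaging m regularized networks: Rubin's rules do not apply to
  penalized edge sets, and averaging selection outcomes mixes models with
  different supports. This is a declared convention, not a reconstruction
  of any published procedure.
* **Degenerate inputs.** Pairs with fewer than three jointly observed
  cases, zero-variance nodes, groups smaller than the node count,
  all-missing columns, and >50%-missing columns are all hard errors with
  the offending pair/node/group named; constant variables in descriptives
  yield an undefined statistic instead of an exception.

## Design decisions that were genuinely open

* **Correlation family.** Only "a correlation matrix" is specified in this
  tradition; weighted Pearson on the codes is the default, weighted
  Spearman (column-wise weighted mid-ranks, then the same pairwise
  machinery) the alternative. Weighted polychoric estimation has no
  established convention and is deliberately out of scope.
* **Bridge symmetry.** BEI is computed strictly between the well-being and
  disability communities, and confounder edges are excluded from both
  sides' bridge sums — the symmetric reading of a definition that is
  usually stated only for one side.
* **"One-step"** bridge influence means direct edges only; no two-step
  propagation.
* **Structure statistic.** The structure-invariance statistic is
  `max|W₁ − W₂|` over node pairs. Published "structural invariance"
  numbers are sometimes reported on other scales; the statistic exposed
  here is the one actually tested by the permutation engine.

## Problem sizes used in the shipped experiments

The test suite runs its replicate batteries at the sizes the corresponding
properties are stated for — e.g. type-I calibration with 200 replicates ×
200 permutations at n = 1500 per group, power with 100 replicates at
n = 3000 per group, stability at n = 10 000 — while using a 30-point λ
grid for the replicate batteries (rejection-rate properties are invariant
to grid resolution because observed and permuted statistics share one
estimator) and the default 100-point grid for single fits.
`scripts/acceptance.R` regenerates the headline analysis on a 6000-
respondent synthetic cohort in a couple of minutes.

## Known limitations

* Bootstrapped percentile CIs of L1-penalized edges are centred on the
  *shrunken* estimate. For a strong edge the EBIC-selected penalty biases
  the estimate downward by roughly the penalty size, which at large n
  exceeds the CI half-width; such intervals quantify sampling variability
  of the regularized estimator, and should not be read as unbiased
  confidence intervals for the unpenalized truth. This is an inherent
  property of penalized estimation, not a solver artefact (the solver is
  verified against dense inversion at λ = 0 and converges to duality gap
  1e-6).
* Ordinal attenuation (above) means absolute edge weights from coded data
  understate latent associations; comparisons *across* groups estimated
  the same way remain meaningful.
* Cross-sectional, undirected: nothing here supports causal or directional
  claims.
* Design-based variance (clustering, stratification, replicate weights) is
  out of scope; weights enter point estimation only.
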