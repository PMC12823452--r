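# bridgenet

Psychometric network analysis of weighted ordinal survey data, built around
the question of how functional-disability domains connect to child and
adolescent mental well-being in household surveys such as those using the
Child Functioning Module (CFM): ten proxy-reported difficulty domains coded
1–4, two well-being items (signs of depression and anxiety) coded 1–5, and
a block of sociodemographic confounders, each respondent carrying a survey
sampling weight.

It is written for epidemiologists and psychometricians who want the full
analysis chain as composable, tested R functions: tibble in, tibble out,
with `tidy()`/`glance()` methods and ggplot2 `autoplot()`s for every result
type.

## The model

Respondent item responses are treated as indicators of a Gaussian graphical
model (GGM). From a weighted available-case correlation matrix `S`, the
graphical lasso estimates a sparse precision matrix by solving

    max_K  log det K − tr(SK) − λ Σ_{i≠j} |k_ij|

(diagonal unpenalized), and the network's edge weights are the regularized
partial correlations `w_ij = −k_ij / √(k_ii k_jj)`. The penalty λ is chosen
on a 100-point log-spaced path by the extended Bayesian information
criterion

    EBIC = −2 L + E log n + 4 E γ log p ,     γ = 0.5 ,

where `E` is the number of nonzero edges. On the selected network the
package computes, per node, the expected influence `EI(v) = Σ_u w_vu` and
the one-step bridge expected influence — the signed sum of a node's edges
crossing between the well-being and disability communities — plus the
global strength `S = Σ_{u<v} |w_uv|`.

Group contrasts (gender; children 5–9 vs adolescents 10–17) are tested by
permuting group labels and re-estimating both networks per permutation:
global strength invariance (`|S₁ − S₂|`), structure invariance
(`max |W₁ − W₂|`), and per-node BEI differences with Benjamini–Hochberg
correction. Robustness comes from non-parametric bootstrap CIs (resampling
respondents with replacement) and case-dropping bootstrap
correlation-stability (CS) coefficients — the largest share of the sample
that can be dropped while subsample centralities still correlate at
r ≥ 0.7 with the full-sample ones (0.25 adequate, 0.5 good). A
chained-equations imputation path (predictive mean matching, m = 10)
provides the missing-data sensitivity analysis.

Because real CFM microdata are registration-gated, the package ships a
synthetic generator (`cfm_spec()`, `simulate_survey()`) that draws ordinal
surveys from known sparse GGMs — latent multivariate Gaussian thresholded
per item, log-normal sampling weights, MCAR missingness, and per-group
edge edits — so every stage can be validated against ground truth.

## Worked example

```r
library(bridgenet)

spec <- cfm_spec(n_per_group = 500, missing_rate = 0.09)
surv <- simulate_survey(spec, seed = 1)       # 2000 respondents, 18 nodes

net <- estimate_network(surv, config = estimator_config(n_lambda = 30))
net
#> Regularized partial-correlation network
#>   18 nodes, 31 edges; lambda = 0.05054 (EBIC gamma = 0.5, n = 2000)

head(dplyr::arrange(centrality(net), dplyr::desc(bei)), 5)
#> # A tibble: 5 × 4
#>   node              community     ei   bei
#>   <chr>             <chr>      <dbl> <dbl>
#> 1 depression        wellbeing  0.472 0.233
#> 2 anxiety           wellbeing  0.453 0.224
#> 3 making_friends    disability 0.253 0.145
#> 4 behaviour_control disability 0.365 0.118
#> 5 accepting_change  disability 0.441 0.112

cmp <- network_compare(surv, "gender",
                       config = estimator_config(n_lambda = 30),
                       n_permutations = 200, seed = 2)
cmp
#> Network comparison: gender = female vs male (n = 1000 / 1000, 200 permutations)
#>   global strength: 1.538 vs 1.774 (diff 0.236, p = 0.6617)
#>   structure invariance M: 0.082 (p = 0.8955)
#>   bridge nodes with BH-adjusted p < 0.05 : none
```

The centrality table reads: in this simulated cohort the two well-being
nodes carry the largest bridge influence, and among disability domains the
social/behavioural ones (making friends, behavioural control, accepting
change) connect most strongly to well-being — the structure the generator's
default truth encodes. At n = 1000 per gender the built-in gender edits are
small, so both invariance tests are non-significant here.

`autoplot(net)`, `plot_centrality(centrality(net))`, `autoplot(cmp)`,
`autoplot(bootstrap_network(...))` and `autoplot(case_dropping_stability(...))`
give the standard figures. `run_study()` executes the whole flow
(descriptives, gender and age networks, comparisons, robustness,
imputation sensitivity) into a directory with a seed-pinned
`manifest.json`; `inst/cli/bridgenet.R` exposes the same stages as shell
subcommands.

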