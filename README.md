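# nichebreadth

Tools for asking how a population's thermal niche breadth is assembled from
the genotypes it contains. Designed for family-structured thermal
performance experiments — populations of full-sibling families grown at a
series of daytime temperatures with a non-negative performance measure such
as relative growth rate (RGR) — like the classic paired-population
monkeyflower (*Mimulus*) growth-chamber studies: 5 closely related species
pairs, one population each, 11–50 families per population, eight regimes
spanning 15–50 °C.

A population can be thermally broad because its genotypes are
general-purpose (each broad), because their thermal optima diverge, or
because they vary in how broad they are. `nichebreadth` implements the full
chain for separating these routes:

* **Curve model.** Each family's thermal performance curve is a
  mode-normalised Kumaraswamy kernel: with t = (x − L)/(U − L),
  g(t) = a·b·t^(a−1)(1 − t^a)^(b−1), and P(x) = h·g(t)/g(t\*) between the
  critical limits L and U, zero outside, with peak h at the analytic
  optimum T_opt = L + t\*(U − L), t\* = ((a−1)/(ab−1))^(1/a). Family
  breadth (B50) is the temperature span with at least 50% of peak
  performance, truncated to the measured 15–50 °C window; population
  breadth is the per-draw envelope, max upper bound − min lower bound
  across families.
* **Hierarchical Bayesian fit** (`fit_tpc()`): zero-inflated
  truncated-normal observation model (structural zeros with probability
  logit⁻¹(γ₀ + γ₁μ) concentrate near the thermal limits), family
  parameters exchangeable around population means, blockwise adaptive
  Metropolis sampling with split-R-hat/ESS diagnostics and a
  posterior-predictive Bayesian p-value.
* **Derived statistics** (`summary()`, `breadth_ratio()`,
  `sd_from_variance()`): per-population posterior means and 95% credible
  intervals of population and family breadth and of the among-family
  variances of T_opt and T_breadth.
* **Hypothesis tests** (`niche_partition()`): three linear mixed-effects
  models of population breadth (on family breadth; on among-family
  variance in T_opt; on among-family variance in T_breadth) with a
  species-pair random intercept, REML via lme4, Satterthwaite p-values,
  Nakagawa marginal/conditional R², and standardised slopes.
* **Synthetic data** (`simulate_tpc_study()`): paired-population studies
  with known truth under generalist / divergent-optima / variable-breadth /
  null scenarios, for validation and power exploration.

## Worked example

The packaged `mimulus_breadths()` table carries the published
per-population estimates (one row per population: breadths, among-family
variances, 95% CIs, species-pair labels a–e). Genotype-level breadth covers
60–86% of population breadth:

```r
library(nichebreadth)
tab <- mimulus_breadths()
round(breadth_ratio(tab), 2)
#>  M. cardinalis    M. parishii M. verbenaceus M. eastwoodiae M. floribundus
#>           0.86           0.77           0.86           0.80           0.69
#>    M. norrisii     M. bicolor  M. filicaulis    M. guttatus  M. laciniatus
#>           0.72           0.60           0.70           0.66           0.62
round(range(sd_from_variance(tab)), 2)   # among-family sd of T_opt, degrees C
#> [1] 1.99 3.48
```

The three hypothesis models (here the two variance predictors; the
family-level model needs per-family breadths, which `run_pipeline()`
produces from raw data):

```r
niche_partition(tab)
#> Niche-breadth partitioning tests (pair-random-intercept LMMs)
#> One-sided slope > 0 rule at alpha = 0.1
#>
#>                 model           slope p_value marginal_r2 conditional_r2
#>   H2_divergent_optima 0.508 +/- 0.213   0.070       0.087          0.931
#>  H3_breadth_variation 0.275 +/- 0.485   0.597       0.014          0.841
#>        std_slope significant
#>  0.291 +/- 0.122        TRUE
#>  0.120 +/- 0.211       FALSE
```

Every unit of among-family variance in thermal optimum adds ~0.51 °C of
population breadth (one-sided p = .035 at the α = .1 rule), while variance
in family breadth predicts nothing (p = .597) — populations accrue breadth
primarily through genotypes with divergent optima. The high conditional vs
marginal R² says species pairs differ far more in breadth than the
predictors explain.

Fitting a simulated population end to end:

```r
sim <- simulate_tpc_population(n_families = 8, seed = 42,
  design = tpc_design(families_range = c(8, 8), reps_range = c(3, 3)))
fit <- fit_tpc(sim$observations, config = tpc_fit_config_reduced(seed = 5))
summary(fit, n_rep = 200)
#> Breadth partitioning summary (posterior mean [95% CI])
#>   pop1 (pair a, 8 families, n = 192)
#>     population breadth 34.47 [32.83, 35.00] C; family breadth 24.95 [22.74, 26.76] C
#>     var(T_opt) 45.42 [28.51, 65.69]; var(T_breadth) 6.41 [1.50, 15.99]; Bayesian p = 0.51
```

`plot(fit)` draws the fitted family curves with the envelope marked;
`run_pipeline(run_config(...))` chains simulate → fit → derive → test into
a results directory with logs and a config hash.

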