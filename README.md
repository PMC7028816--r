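# cfimpact

Bayesian counterfactual impact evaluation for demand time series: did a
discrete event (a movie release, a campaign, a policy change) shift demand
for something — searches for it, purchases of it, visits to places that show
it?

The package fits a counterfactual regression **only to pre-intervention
data**, relating the focal series to reference series that share the
background forces but not the intervention, then forecasts the
post-intervention window from the full posterior predictive distribution.
Impact at each post-intervention period is summarised as

* the **ratio** of the observed outcome to its counterfactual expectation,
  `observed / expected`, with 50% and 90% equal-tailed credible intervals
  (values above 1 = higher than expected), and
* the **exceedance probability** `Pr(observed > expected)` under the
  posterior predictive distribution.

Three observation models cover the three demand stages:

| family | outcome | model |
|---|---|---|
| `beta` | relative search frequency in [0, 1] | `y ~ Beta(mu, phi)` (mean–precision: shapes `mu*phi`, `(1-mu)*phi`), `logit(mu) = X beta`, reference main effects + pairwise interactions |
| `negbin` | monthly import counts | NB2 GLM: `log(mu) = X beta`, variance `mu + mu^2/phi`, zero-dominated references dropped |
| `seasonal_trend` | monthly visitation (positive) | `log(y) ~ Normal(M beta + s(T), sigma^2)`: January-base month factor + penalized B-spline trend over standardized decimal time |

with weakly informative priors — `Normal(0, 2)` slopes, `Normal(0, 10)`
intercept, Half-Student-t(3, 0, 25) on `phi`, Half-Student-t(3, 0, 2) on
`sigma` and the spline's smoothness SD. Posteriors come from the package's
own No-U-Turn sampler (Rcpp, dense adapted metric; 4 chains × 2000
iterations, half warm-up, by default) and every fit is gated on split-chain
R-hat < 1.05 and effective sample size > 100 for all parameters.

Because the motivating datasets are proprietary, the package ships
synthetic-data generators with known ground truth for all three panel
kinds, plus a replicate calibration harness (`run_calibration_study()`)
that verifies null calibration, interval coverage and detection power of
the whole pipeline.

## Worked example

Simulate a weekly search-interest study in which the intervention doubles
the odds of searching at week 1 (×2.1, decaying to nothing by week 7), then
evaluate it:

```r
library(cfimpact)

sim <- generate_search_panel(
  scenario_config("search", seed = 7,
                  effect_profile = transient_effect(peak = 2.1, duration = 7)))
sim$study
#> <cf_study> intervention at 2016-02-14: 110 pre / 10 post periods

fit <- evaluate_impact(sim$study, model_spec("beta"), sampler_config(seed = 7))
glance(fit)
#> # A tibble: 1 × 8
#>   family n_pre n_post converged max_rhat min_n_eff p_exceed_first ratio_median_first
#>   <chr>  <int>  <int> <lgl>        <dbl>     <dbl>          <dbl>              <dbl>
#> 1 beta     110     10 TRUE          1.00     2925.          0.745               1.31

tidy(fit)[, c("date", "observed", "ratio_median", "ratio_lo90",
              "ratio_hi90", "p_exceed")]
#> # A tibble: 10 × 6
#>    date       observed ratio_median ratio_lo90 ratio_hi90 p_exceed
#>    <date>        <dbl>        <dbl>      <dbl>      <dbl>    <dbl>
#>  1 2016-02-14    0.142        1.31       0.698       2.88    0.745
#>  2 2016-02-21    0.320        1.64       1.04        2.86    0.964
#>  3 2016-02-28    0.386        1.48       1.02        2.37    0.96
#>  4 2016-03-06    0.212        1.37       0.825       2.71    0.830
#>  5 2016-03-13    0.206        1.80       0.990       4.01    0.946
#>  6 2016-03-20    0.138        1.28       0.678       2.93    0.712
#>  7 2016-03-27    0.147        1.02       0.595       2.05    0.518
#>  8 2016-04-03    0.167        1.01       0.614       1.96    0.517
#>  9 2016-04-10    0.202        1.28       0.768       2.55    0.766
#> 10 2016-04-17    0.118        0.932      0.530       2.01    0.436
```

Reading the output: in the weeks right after the intervention the observed
search frequency runs 1.3–1.8× the counterfactual expectation with
exceedance probabilities up to 0.96; by weeks 7–10 the ratio is back around
1 and the exceedance probability around 0.5 — the injected transient effect,
recovered with honest uncertainty (any single replicate is noisy; the
calibration harness quantifies behaviour across replicates).
`autoplot(fit)` draws the observed series over the counterfactual bands and
`autoplot(fit, type = "ratio")` the ratio panel. A thin command-line wrapper
(`exec/cfimpact`) exposes the same pipeline as `simulate`, `evaluate` and
`calibrate` subcommands.

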