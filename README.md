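# circamix

Mixed-effects cosinor models for longitudinal circadian data.

Wearable devices measure physiological signals with a daily rhythm — heart
rate variability (HRV) is the classic case — sparsely and at irregular
clock times across many days per person. `circamix` is for analysts who
want to estimate that rhythm and compare it across groups while properly
accounting for the repeated measurements within each subject: it fits the
single-component cosinor model inside a linear mixed-effects framework,
recovers the nonlinear rhythm parameters per covariate group, and tests
group differences with a bootstrap.

## The model

The daily rhythm is modelled as

    Y(t) = M + A cos(2πt/τ + φ) + e(t)

with period τ (24 h), MESOR `M` (rhythm-adjusted mean), amplitude `A`
(half the peak-to-trough extent) and acrophase `φ` (the phase angle; the
peak occurs at −φτ/2π hours). Recoding time as `x = cos(2πt/τ)`,
`z = sin(2πt/τ)` makes the model linear, `Y = M + βx + γz + e`, with
`β = A cos φ`, `γ = −A sin φ`. For longitudinal data this linear model is
extended with subject-level random effects (random MESOR, or random MESOR
plus rhythm coefficients) and categorical covariates interacting with `x`
and `z`, fitted by REML via `lme4`. Group-level `(M, A, φ)` are obtained
from estimated marginal means of `(M, β, γ)` over the covariate grid
(emmeans-style specifications such as `~COVID` or `~bmi_cat | sex`) and
the inverse relationship above. Confidence intervals and p-values for
group differences in `M`, `A` and `φ` come from a parametric (or
subject-resampling) bootstrap that refits the whole pipeline per
replicate; acrophase differences are wrapped to the minimal circular
branch.

## Worked example

Simulate an HRV-like study (60 subjects, 8 irregular daytime observations
each) in which infection lowers the MESOR by 5 ms, the amplitude by 4 ms,
and delays the acrophase by 0.5 rad, then recover those differences:

```r
library(circamix)

d <- simulate_cosinor_data(
  n_subjects = 60, obs_per_subject = 8,
  factors = list(covid = c("neg", "pos")),
  truth = data.frame(covid = c("neg", "pos"),
                     mesor = c(52, 47), amplitude = c(10, 6),
                     acrophase = c(-1.2, -1.7)),
  re_sd = c(8, 0, 0), residual_sd = 6, seed = 42)

f <- fit_cosinor_mixed(d, factors = "covid")   # Y ~ covid*(x+z) + (1|id)
cosinor_emm(f, ~covid)
#>   covid mesor amplitude acrophase peak_time degenerate extrapolated
#> 1   neg 52.69     9.905    -1.314     5.018      FALSE        FALSE
#> 2   pos 45.96     5.033    -1.530     5.845      FALSE        FALSE

b <- bootstrap_cosinor(f, ~covid, nsim = 500, seed = 1)
contrasts_ci(b)
#>    contrast       parameter estimate  lower  upper       p stars
#> 1 neg - pos           mesor    6.730  2.919 10.764 0.00399    **
#> 2 neg - pos       amplitude    4.872  2.997  6.471 0.00399    **
#> 3 neg - pos       acrophase    0.217 -0.176  0.625 0.27146
#> 4 neg - pos acrophase_hours   -0.827 -2.386  0.674 0.27146
```

Reading the output: the negative group's fitted rhythm has MESOR 52.7 ms,
amplitude 9.9 ms and peaks at 5.0 h; the infected group sits 6.7 ms lower
(95% CI 2.9–10.8, p ≈ 0.004) with a 4.9 ms smaller amplitude — both close
to the generating truth of 5 and 4. The acrophase difference (0.22 rad ≈
0.8 h earlier peak in this realization, truth 0.5 rad) is not
distinguishable from zero at this sample size. `means_ci(b)` gives
per-group intervals, `predict_curve(f, ~covid)` the fitted daily curves,
and `plot_cosinor_curves(f, ~covid, data = d)` a basic figure.

A command-line interface over the same functions (subcommands `simulate`,
`fit`, `means`, `contrasts`, `curve`, YAML config) ships in
`inst/cli/circamix.R`.

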