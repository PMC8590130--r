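---
title: "Mixed-effects cosinor models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-effects cosinor models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Many physiological signals measured by wearables — heart-rate variability
(HRV) is the canonical example — follow a roughly sinusoidal daily rhythm,
but devices sample them sparsely and at irregular clock times across many
days. The single-component cosinor model describes one day's rhythm as

$$Y(t) = M + A\cos\!\left(\frac{2\pi t}{\tau} + \phi\right) + e(t),$$

with period $\tau$ (24 h for circadian work), MESOR $M$ (the
rhythm-adjusted mean), amplitude $A$ (half the peak-to-trough extent) and
acrophase $\phi$ (the phase angle fixing the clock time of the peak,
$t_{peak} = -\phi\tau/2\pi$). The model is nonlinear in $(A, \phi)$ but
becomes linear after recoding time into
$x = \cos(2\pi t/\tau)$, $z = \sin(2\pi t/\tau)$:

$$Y(t) = M + \beta x_t + \gamma z_t + e(t), \qquad
  \beta = A\cos\phi,\; \gamma = -A\sin\phi.$$

For longitudinal data — the same subject observed over many days — the
observations within a subject are correlated, so `circamix` extends the
linearized model to a linear mixed model. With a categorical covariate $C$
(any number of levels, entered with treatment coding) the fixed part is

$$Y_{it} = M + \alpha_0 C_i + (\beta + \alpha_2 C_i)\,x_{it}
          + (\gamma + \alpha_3 C_i)\,z_{it} + W_{it}\theta_i + e_i(t),$$

where $\theta_i \sim N(0, \Sigma)$ are subject-level random effects and
$e_i(t) \sim N(0, s^2)$. Every factor (or interaction cell) therefore gets
its own MESOR offset and its own rotation of $(\beta, \gamma)$ — i.e. its
own amplitude and acrophase. Two random structures are supported, the two
used in practice for daily rhythms: a random MESOR per subject
(`(1 | id)`), or random MESOR plus random rhythm coefficients
(`(1 + x + z | id)`) with an unstructured $\Sigma$. Estimation is REML by
default (`reml = FALSE` gives ML for likelihood comparisons), delegated to
`lme4`.

Because the likelihood is that of a standard linear mixed model, missing
observations are handled by available-case analysis: rows missing the
response or a model covariate are dropped (with a logged count), and the
fit remains valid under the missing-at-random assumption. No imputation is
performed.

# Marginal means and group-level rhythm parameters

Group-level parameters are defined through estimated marginal means in the
`emmeans` sense. For a grid specification such as `~COVID` or
`~bmi_cat | sex`, each grid cell fixes its factors at their levels and
averages all other model factors over their levels — equal weights by
default; `weights = "proportional"` uses the observed joint frequencies of
the averaged factor combination instead. Each cell's
$(M_g, \beta_g, \gamma_g)$ is then an exact linear combination $L\hat c$
of the fixed-effect coefficients, which makes the construction invariant
to the choice of reference levels. The nonlinear parameters follow from
the inverse relationship

$$A_g = \sqrt{\beta_g^2 + \gamma_g^2}, \qquad
  \phi_g = \operatorname{atan2}(-\gamma_g, \beta_g)
  \;\text{mapped into } (-2\pi, 0].$$

The acrophase range $(-2\pi, 0]$ is the standard cosinor-literature
convention; it keeps the implied peak time $-\phi\tau/2\pi$ nonnegative,
and peak time in hours is always co-reported for interpretability. When
$A_g = 0$ the acrophase is undefined: it is set to 0, flagged
`degenerate`, and downstream phase intervals for that cell are reported as
`NA`. Grid cells whose factor combination never occurs in the data are
still computed — the model defines them — but flagged `extrapolated` with
a warning.

# Bootstrap inference for the nonlinear parameters

Hypotheses that are linear in the coefficients (differences of MESORs, of
$\beta$s, of $\gamma$s) can be tested by Wald z-tests from the coefficient
covariance (`wald_test()`; no Satterthwaite/Kenward–Roger correction is
applied, so p-values are asymptotic). Amplitude and acrophase are
nonlinear, and their sampling distributions can be markedly non-normal —
amplitude is bounded below, acrophase is circular — so interval estimation
and testing use a bootstrap that repeats the entire pipeline per
replicate: resample, refit the mixed model, recompute the marginal means,
invert to $(M, A, \phi)$, and take all pairwise differences between cells
within each conditioning stratum. A delta-method alternative is
deliberately not offered as a default path.

Two resampling schemes are provided:

* **parametric** (default): responses are simulated from the fitted model
  — fixed effects, estimated $\Sigma$, estimated $s^2$ — and the model is
  refitted. This is the conventional bootstrap for mixed models and keeps
  the design (subjects, times) fixed.
* **cluster**: whole subjects are resampled with replacement. This makes
  fewer distributional assumptions but changes the realized design per
  replicate and can drop factor levels in small samples.

Failed refits are skipped and counted, never silently retried (retrying
would bias the bootstrap distribution); if more than 10 % fail the result
is flagged unreliable, and if all fail an error is raised. The default
replicate count is 500 and the default interval level 0.95. Fixing `seed`
makes every draw reproducible bit-for-bit.

Intervals are percentile intervals (type-7 quantiles). For the acrophase,
quantiles of raw angles are meaningless across the $-2\pi/0$ branch cut,
so draws are first unwrapped to the branch nearest the full-data point
estimate; if the unwrapped draws still span more than half a cycle the
cell is flagged `wide_phase`. Acrophase differences are wrapped to the
minimal circular branch $(-\pi, \pi]$ (ties at exactly half a cycle map to
$+\pi$), and are reported both in radians and in hours (wrapped to half a
period), since an unwrapped difference of circular quantities is
meaningless.

The bootstrap p-value uses the add-one sign-count construction
$$p = \min\!\left(1,\; \frac{2\min(\#\{d \le 0\} + 1,\; \#\{d \ge 0\} + 1)}
  {B + 1}\right),$$
which never returns exactly zero and is monotone in the sign imbalance of
the draws. Star labels follow the conventional strict thresholds
(`***` < 0.001, `**` < 0.01, `*` < 0.05, `+` < 0.1). P-values across the
pairwise contrasts are **not** adjusted for multiplicity; with many cells
(e.g. three BMI categories within each sex) users should apply their own
correction if family-wise control is wanted.

# The synthetic-data generator

`simulate_cosinor_data()` generates data from exactly the model the fitter
assumes, which is what makes it usable for parameter-recovery, coverage
and type-I-error studies: subjects are assigned to covariate cells by
given proportions, each cell has a true $(M, A, \phi)$ mapped to
$(M, \beta, \gamma)$, subject-level deviations are drawn on the *linear*
scale from $N(0, \Sigma)$, and Gaussian residual noise is added. Drawing
random effects on the linear scale matches the fitted model exactly;
subject-level amplitude and acrophase then follow a derived, non-Gaussian
distribution (e.g. subject amplitude is a noncentral-chi-type variable).

Defaults emulate an HRV-like wearable study: MESOR around 50 ms, amplitude
6–10 ms, overnight acrophase, subject MESOR SD 8 ms, small rhythm-
coefficient SDs (2 ms), residual SD 10 ms, and a `"daytime"` sampling
scheme that draws 85 % of observation times from a normal centred at 13 h
(SD 4 h) truncated to 6–23 h, plus a 15 % uniform background — mimicking
app-driven measurements concentrated in waking hours. Missingness is
independent thinning (MCAR), the simplest MAR mechanism.

What the generator does *not* emulate: non-Gaussian or heteroscedastic
residuals, within-day autocorrelation beyond the random effects,
informative (MNAR) missingness, day-to-day drift of the rhythm, and
harmonics beyond the single 24-h component. Tests passing on generated
data therefore validate the estimation machinery under the model's own
assumptions, not robustness to their violation.

# Numerical choices

* **Optimizer.** `lme4` with the post-fit finite-difference derivative
  check disabled (`cosinor_lmer_control()`): for the small models used
  here that check dominates runtime while duplicating the optimizer's own
  convergence code, which is still consulted; bootstrap refits reuse the
  fitted model structure via `lme4::refit()`. Singular-fit messages are
  suppressed because boundary fits ($\hat\Sigma$ at zero) are an expected,
  explicitly flagged outcome — at the boundary the fixed effects coincide
  with ordinary least squares, which is verified against the closed form
  $(X^\top X)^{-1}X^\top Y$ in the test suite.
* **Rank checking.** The fixed design is QR-checked before fitting and
  aliased columns are reported by name, rather than letting columns be
  dropped silently.
* **Validation problem sizes.** The package's simulation-based checks use
  100 subjects × 10 observations for parameter recovery (bootstrap
  B = 200), and 200 replicates at 40 subjects × 8 observations with
  B = 199 for the coverage and null-calibration studies; the acceptance
  script reports a 100-replicate, B = 99 version of the same studies.
  These sizes are typical of a mid-sized wearable cohort and give
  Monte-Carlo error small enough for the 88–99 % coverage band and the
  binomial band around a 5 % rejection rate used in the checks.

# Known limitations

* Single-component cosinor only; multi-harmonic or non-sinusoidal
  waveforms are out of scope.
* Categorical covariates only in interaction with the rhythm terms;
  continuous moderators of amplitude/phase are not supported.
* Random structures are limited to the two practical forms above; no
  nested/crossed random effects or residual autocorrelation.
* Wald tests are asymptotic (no small-sample df correction); bootstrap
  intervals are percentile (no BCa/studentized variants).
* No multiplicity adjustment across pairwise contrasts.
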