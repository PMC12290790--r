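---
title: "Hierarchical multivariate modelling of dynamic PET data with petpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical multivariate modelling of dynamic PET data with petpool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

petpool quantifies dynamic PET time-activity curves (TACs) with
compartmental models and analyses group differences in binding potential
with hierarchical multivariate Bayesian models. This vignette describes
the models, the priors and tunable parameters, the synthetic cohort
generator that stands in for clinical data, the numerical choices made,
and the limitations of each.

## The quantification problem

A dynamic PET measurement of a receptor radioligand yields, for each
subject and brain region, a TAC: the decay-corrected radioactivity
concentration averaged over each acquisition frame (here 20 frames over
110 minutes: 3×20 s, 3×1 min, 3×2 min, 2×5 min, 9×10 min). With arterial
blood sampling, the metabolite-corrected parent plasma curve
$C_p(t)$ serves as the input function of a two-tissue compartment model
(2TCM) with rate constants $K_1$ (plasma→tissue, mL/cm³/min), $k_2$
(efflux), $k_3$, $k_4$ (exchange with the specifically bound
compartment), and a blood-volume fraction $v_B$; whole plasma is used as
the whole-blood proxy in the $v_B$ term, and the model frame prediction
is the time-average of the continuous solution over the frame (the
early 20-second frames make midpoint evaluation noticeably biased,
which is why averaging is used).

Binding is summarized by outcome measures defined from the rates:

* $BP_{ND} = k_3/k_4$ — specific binding relative to non-displaceable
  uptake;
* $V_{ND} = K_1/k_2$, $BP_P = BP_{ND} \cdot V_{ND}$,
  $V_T = V_{ND}(1 + BP_{ND})$;
* $BP_F = BP_P / f_P$, where $f_P$ is the plasma-free fraction measured
  by ultrafiltration.

The model can be parameterized with any of $BP_{ND}$, $BP_P$ or $BP_F$
as the binding parameter (log scale), the remaining log-parameters being
$\log K_1$, $\log V_{ND}$, $\log k_4$ and $\log v_B$. For the $BP_F$
parameterization the tissue input is $f_P C_p(t)$, so the transfer
parameters become $K_1/f_P$ and $V_{ND}/f_P$; the $v_B$ term always uses
unscaled whole plasma. Without blood data, the simplified reference
tissue model (SRTM) with parameters $R_1$, $k_2'$ and $BP_{ND}$ provides
indirect quantification against a reference-region curve.

Conventional practice fits each TAC separately by weighted nonlinear
least squares (NLS), with weights
$w_i = \sqrt{\Delta_i \cdot \tilde{y}_i}$ (frame duration times the
decay-uncorrected frame activity, carbon-11 half-life 20.364 min),
normalized to mean one. Direct estimation of $BP_{ND}$ from 2TCM rate
constants is notoriously unstable per TAC — which is precisely the
motivation for the hierarchical approach.

## The simultaneous hierarchical model

`build_simba_model()` + `fit_simba()` fit **all TACs of a study at
once**. For TAC $t$ (subject $i$, region $r$), the five log kinetic
parameters $\lambda_t$ are latent and decomposed as

$$\lambda_{tp} = x_{tp}^\top \beta_p + \upsilon_{r p} + \tau_{i p} +
\gamma_{tp},$$

* **Fixed effects** $\beta$: the binding-potential parameter gets
  region intercepts, sex, age (centered, per decade) and a
  group-by-region interaction *without* an overall group term, so each
  coefficient is directly the log-scale group difference in that
  region. $\log K_1$ and $\log V_{ND}$ get intercept + age + sex
  ($\log k_2'$ for the SRTM parameter set); $\log k_4$ and $\log v_B$
  get intercepts only.
* **Region deviations** $\upsilon$ (all non-BP parameters): partially
  pooled, sum-to-zero per draw, half-normal scale priors.
* **Individual deviations** $\tau_i$: a full multivariate normal across
  all five parameters with estimated covariance — the key device that
  lets subject-level disturbances (for example a mis-measured $f_P$
  scaling $K_1/f_P$, $V_{ND}/f_P$ and $BP_F$ together) be absorbed as a
  correlated individual deviation rather than leaking into group
  contrasts.
* **TAC deviations** $\gamma$: independent per parameter
  (region-by-individual interaction).

The measurement model is Student-t on the frame scale,
$y_{tf} \sim t_\nu(\mu_{tf}(\lambda_t),\ s_t / w_{tf})$ with $\nu$
estimated (lower-bounded at 3), per-TAC error scales $s_t$ lognormally
pooled, and the frame weights entering as inverse scales — the same
weighting scheme as the NLS comparator.

### Priors

* Group-difference coefficients: Normal(0, 0.2) on the log scale. This
  prior puts 64% of its mass on differences below 20%, 81% below 30%,
  and 9% above +30% (one-sided). For a 10% difference the two-sided
  mass is ≈37% and the one-sided mass above +10% is ≈18%; both
  conventions are exposed by `prior_mass()` because published
  descriptions of this prior mix the two for this one cutoff.
* Global intercepts: normal priors centred on pooled quick NLS
  estimates of the same data (medians per region for BP), SD 1 — a
  data-driven default that can be overridden through the `priors`
  argument.
* Random-effect SDs: half-normal(0, 0.3) for $K_1$, $V_{ND}$ and BP;
  half-normal(0, 0.2) for $k_4$ and $v_B$.
* Individual-level covariance: inverse-Wishart with df $= p+3$ and
  prior-mean SDs of 0.2. An LKJ prior would be the more common choice
  in Hamiltonian Monte Carlo frameworks; the inverse-Wishart is used
  here because it gives a conjugate Gibbs block, and at these dimensions
  and sample sizes the difference is immaterial next to the likelihood.

### Sampling

The sampler is Metropolis-within-Gibbs, written for this model:

1. each TAC's 5-dimensional latent block $\lambda_t$ is updated by an
   adaptive random-walk Metropolis step against the analytic 2TCM frame
   likelihood (computed in C++ via exact exponential-integrator
   convolution on a 2-second grid; the running integral of the
   convolution is computed in closed form, so frame averages carry no
   quadrature error beyond the piecewise-linear input representation);
2. given the latents, every hierarchy level — fixed effects, region and
   individual deviations, covariances and the gamma-mixture latents of
   the Student-t — has a conjugate full conditional and is Gibbs-updated
   (random-effect SDs use scalar log-scale Metropolis steps).

Proposal scales adapt toward ≈0.3 acceptance during warmup and are then
frozen. Chains run sequentially from `seed + chain - 1`; split R-hat and
a crude autocorrelation-based effective sample size are reported for
every scalar, with a warning when a fixed effect exceeds R-hat 1.01.
Default settings are 4 chains × (1000 warmup + 1000 draws); the tests
and the acceptance script use 1–2 chains × (250–500 + 250–500), which is
enough for posterior means of contrasts but leaves visible R-hat noise —
the warning is informative, not an error.

## The multivariate analysis of pre-estimated parameters

`fit_pumba()` applies the same fixed-effect and random-effect structure
to a table of per-TAC NLS estimates treated as a multivariate-normal
response (SRTM's $\{\log R_1, \log k_2', \log BP_{ND}\}$ by default; a
2TCM parameter set works identically). The residual covariance across
parameters is estimated in full. Everything is conjugate, so this is a
pure Gibbs sampler and very fast. Estimation uncertainty of the NLS
inputs is *not* propagated — estimates enter as data. That is a known
limitation of the approach: when per-TAC estimates are extremely noisy
(direct 2TCM $BP_{ND}$ in a small region), information is lost relative
to the simultaneous model, which is why the simultaneous model is the
default for 2TCM outcomes and the parameter-level model is used for
SRTM, where no TAC-level likelihood is available in this package.

## Group contrasts and regional specificity

`group_contrasts()` transforms group-by-region coefficients to percent
differences, $100(e^\beta - 1)$, with 80%/95% intervals and the
directional probability $P[\beta>0]$; the identical summary shape is
produced for the univariate mixed-model comparator
(`fit_univariate_lme()`, which fits
`log BP ~ 0 + region + sex + age + region:group + (1 | subject)` with
lme4). No multiplicity correction is applied to regional contrasts;
intervals are reported per region.

`rn_vs_projection()` refits the binding model with one overall effect
for the raphe-like region and one for the mean of the serotonin
projection regions per patient group, plus random slopes over projection
regions; it reports $P[\beta_{RN} - \beta_{proj} > 0]$ and the
random-slope SD, the quantity that measures how uniform the projection
effects are.

`fp_drift_analysis()` regresses $\log f_P$ on group with and without a
penalized cubic-regression-spline smooth of scan date (basis dimension
10, smoothing parameter by GCV, fitted with mgcv). The exact thin-plate
REML smoother of the original analysis is deliberately not reproduced;
what matters for the inferential logic — a smooth assay drift can
masquerade as group differences when groups are sampled inhomogeneously
over calendar time — is insensitive to the basis, and the package checks
exactly that logic.

## The synthetic cohort generator

No clinical PET data of this kind are publicly deposited, so
`simulate_cohort()` generates studies with the statistical structure the
analysis assumes, and the test suite and acceptance script run entirely
on it. Defaults (all overridable in `cohort_config()`):

* **Cohort**: 57 healthy volunteers (HV), 50 not-recently-medicated
  (NRM) and 53 antidepressant-exposed (AE) patients; age ~ N(38, 13)
  truncated to 18–70, ≈56% female; injected dose lognormal around
  7 mCi.
* **Regions**: eight serotonin-receptor-rich regions (DLPFC, MPFC, ACC,
  PCC, INS, HIP, AMY) plus a raphe-like region `RN`; optionally
  cerebellar-like `CGM` and the white-matter reference `CWM`.
* **Kinetics**: region-mean parameters chosen to give plausible
  receptor-antagonist-like curves — low non-displaceable distribution
  volume ($V_{ND} \approx 0.6$, ≈15% lower in RN, 35% lower in CWM),
  $BP_{ND}$ between 2.2 (RN) and 3.5 (HIP), very low specific binding
  in the reference regions, $k_4 = 0.04$/min, $v_B = 5\%$. These are
  generator defaults calibrated qualitatively, not measured values.
* **Between-subject structure**: log-scale SDs 0.15/0.20/0.25/0.10/0.15
  for $K_1/V_{ND}/BP/k_4/v_B$ with moderate positive cross-parameter
  correlations, plus TAC-level jitter of 0.03–0.05.
* **Group effects**: NRM +0.15 on log BP in RN and +0.075 in projection
  regions (the raphe effect double the projection effect); AE null.
* **$f_P$**: base 0.07 with two regimes. With the confound toggle on
  (default), measured $f_P$ has *no* true group offsets but drifts
  smoothly downward over the study years (sigmoid, total ≈−0.5 on the
  log scale) while groups are sampled inhomogeneously (HV ≈2002 <
  AE ≈2004 < NRM ≈2006), producing apparent group differences of the
  observed ordering HV > AE > NRM; with the toggle off, dates are
  homogeneous and explicit group offsets are applied.
* **Noise**: frame SD = 5% of the TAC's time-average divided by the
  mean-one frame weight (so noise follows the weighting scheme's
  variance model exactly), tripled in the raphe-like region;
  pre-arrival frames get a floor weight of 0.1 in the noise model.

What the generator does **not** emulate: arterial input measurement
error and dispersion/delay (the AIF is a known smooth Feng-type curve,
linear rise then tri-exponential decay, with a Hill-type parent
fraction), scanner resolution and partial-volume effects, motion,
violated compartmental assumptions, and attenuation. Passing tests on
these cohorts therefore demonstrates the statistical machinery —
shrinkage, calibration, confound absorption — under a well-specified
forward model, not robustness to every artefact of real data. In
particular, per-TAC NLS performs better on these clean curves than on
real clinical data, which compresses the measured advantage of the
hierarchical model relative to what harsher, real-calibrated noise
would show.

## Numerical choices

* Model grid: 1/30 min during fitting (consistent between generation
  and fit), 1/480 min in the standalone forward solvers, where
  agreement with adaptive ODE integration to below $10^{-6}$ relative
  error is verified in the tests.
* NLS: bounded Levenberg-Marquardt on the log scale (rates in
  $[10^{-4}, 5]$, $v_B \le 0.3$, product and $f_P$-scaled parameters
  proportionally wider), data-driven starts plus ≥5 jittered restarts,
  ties broken toward the smaller binding potential; non-convergence is
  flagged, never thrown; each TAC is seeded independently so one
  degenerate curve cannot perturb another's fit.
* Degenerate inputs: all-zero TACs get uniform weights (with a warning)
  and a flagged NLS result; single-region or single-group designs drop
  the inestimable columns; one observation per subject collapses the
  mixed model to ordinary regression.
* The 2TCM discriminant $(k_2+k_3+k_4)^2 - 4k_2k_4$ is non-negative for
  positive rates; a guard clamps tiny negative values from floating
  arithmetic.

## Power analysis utilities

`power_n_per_group(d, power, alpha)` computes the smallest per-group n
for a two-sided two-sample t-test by noncentral-t iteration, and
`prob_superiority(d)` returns $\Phi(d/\sqrt{2})$. For a Cohen's d of
0.32 these give n = 155 per group at 80% power and a probability of
superiority of 59.0%. Published analyses of comparable effect sizes
report slightly different values (e.g. resampling-based probabilities
near 58.7% and n near 158) because they propagate posterior uncertainty
in d rather than plugging in a point value; the closed-form utilities
here intentionally implement the textbook definitions, and the
difference is documented rather than reconciled.

## Known limitations

* The simultaneous model is 2TCM-only; reference-tissue likelihoods are
  not implemented, so SRTM results flow through the parameter-level
  model.
* Random-walk updates of the latent kinetic blocks mix more slowly than
  gradient-based samplers; at the reduced chain lengths used in tests,
  fixed-effect R-hats of 1.1–1.5 are common. Contrast posterior means
  are stable well before interval endpoints are.
* The TAC-level deviations are uncorrelated across parameters by
  construction (only the individual level carries the full covariance);
  whether the original analyses correlated them is unknown, and the
  choice is conservative.
* Measurement uncertainty of NLS inputs to the parameter-level model is
  ignored, as noted above.
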