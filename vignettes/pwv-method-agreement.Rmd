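---
title: "Estimated versus transit-time measured pulse wave velocity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimated versus transit-time measured pulse wave velocity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvagree)
```

`pwvagree` simulates and analyses the comparison of two routes to aortic
pulse wave velocity (PWV): a single-cuff device *estimate* driven by entered
age and blood pressure, and a transit-time *measurement* built from
electro- and mechanocardiographic fiducials. This vignette is the package's
own account of the models, their calibration, and the numerical choices —
what the simulations emulate, what they deliberately do not, and therefore
what a passing test suite does and does not establish about real data.

## The two outcome models

**True aortic PWV.** Ground truth for each simulated subject is linear in
age with additive noise,

$$v(a) = 3.48 + 0.04\,a + \varepsilon, \qquad \varepsilon \sim N(0,\, 0.33^2)\ \text{m/s},$$

so the expectation at age 33 is 4.80 m/s and, for an age SD near 9 years,
age explains roughly half the variance
($R^2 = (0.04\cdot9)^2 / ((0.04\cdot9)^2 + 0.33^2) \approx 0.54$). This is a
deliberately weak age dependence: real aortas differ in stiffness at the
same age, and that residual spread is exactly what a useful device would
need to resolve.

**The device surrogate.** The proprietary estimation algorithm inside
single-cuff monitors is not public; no attempt is made to reverse-engineer
it. Instead the package uses a calibrated surrogate whose deterministic core
is a quadratic in entered age $a$ and mean arterial pressure $m$:

$$f(a, m) = c_0 + c_1 a + c_2 a^2 + c_3 (m - 90),$$

with defaults $c_0 = 5.87$, $c_1 = -0.0656$, $c_2 = 0.001835$,
$c_3 = 0.028$. The vertex of the age quadratic sits at
$-c_1/(2c_2) \approx 17.9$ years, below the valid domain (ages 18–100), so
$f$ is strictly increasing in both arguments. The constants were obtained by
moment matching: requiring the *cohort expectation*
$E[f] = c_0 + c_1\mu_a + c_2(\mu_a^2 + \sigma_a^2) + c_3(E[m] - 90)$ —
note the Jensen term $c_2\sigma_a^2$ — to equal 5.8 m/s for the bedrest
cohort (age 33 ± 9, MAP 88.3 mmHg) and 8.3 m/s for the athlete cohort
(age 56 ± 11, MAP 94.7 mmHg), with a third anchor of ≈ 12.4 m/s at entered
age 80 and MAP 90 fixing the curvature. A consequence worth flagging: the
published cohort means are reproduced by cohort *expectations*, not by point
evaluations of $f$ at the mean age.

A measurement adds two noise layers (`estimate_pwv_protocol()`): a
per-subject deviation $b \sim N(0, \sigma_b^2)$, drawn once per person
(the device's reproducible offset for that person), and per-repetition noise
$e_i \sim N(0, \sigma_r^2)$, with $\sigma_b = \sigma_r = 0.10$ m/s. The
reported estimate is the mean of three repetitions, hence has variance
$\sigma_b^2 + \sigma_r^2/3$ around the core. Holding $b$ fixed within a
person is what lets a single subject display an almost perfect entered-age
dependence ($R^2 \ge 0.996$) while cohorts show additional spread.

## Cohort generation

`draw_cohort()` draws, per subject: age from a truncated normal; mean
arterial pressure with a within-cohort age trend
$\mathrm{MAP} = \alpha + 0.35\,a + N(0, 6^2)$ mmHg, where the intercept
$\alpha$ is anchored per preset so that the cohort MAP mean equals the value
implied by the preset's published cuff pressures (via the standard
$\mathrm{MAP} = \mathrm{DBP} + \mathrm{PP}/3$ convention); systolic and
diastolic pressure recovered from MAP and an independent pulse-pressure
draw; BMI, heart rate, sex; isovolumetric contraction time
$\mathrm{ICT} \sim N(60, 10^2)$ ms truncated to [30, 120] ms; and
jugulum-to-thigh-cuff distance $N(1.00, 0.05^2)$ m truncated to
[0.8, 1.2] m. ICT and distance distributions are physiologically plausible
defaults; published cohort tables do not constrain them. All randomness
flows from a single integer seed through a documented splitting scheme
(cohort → subject → channel), so identical configurations are byte-identical.

The MAP age trend deserves a comment: if MAP were independent of age, the
surrogate's MAP term could not contribute to the high estimated-PWV–age
correlations seen in practice while simultaneously matching the published
cohort MAP means. A slope of 0.35 mmHg/yr with 6 mmHg residual SD satisfies
both.

**The bedrest preset's age clip.** The bedrest cohort is published as age
33 ± 9 within 24–55 years. A normal with SD 9 truncated to [24, 55] has a
realized SD of only 6.9 — no unimodal distribution on that interval with
mean 33 can reach SD 9 — and with the shrunken SD every downstream
age-dependence statistic (measured-PWV–age $R^2$, estimated-vs-measured
$R^2$) falls well short of the published values. Because every statistic the
package computes depends on the age *moments*, the preset keeps mean 33 and
SD 9 and uses a wide adult plausibility clip [18, 70]; the published 24–55
is treated as the descriptive range of one real sample of 24 people, not as
a generator constraint. The same logic applied to the athlete preset is
harmless: clipping N(56, 11²) at the published [35, 86] shaves the SD only
to 10.1.

## Waveform synthesis and fiducial detection

`synthesize_recording()` renders each subject into three uniformly sampled
channels whose *timing* is exact by construction: Gaussian QRS complexes
(≈ 20 ms wide) at each R-peak; a half-sine Doppler ejection envelope
starting exactly at valve opening ($t_R + \mathrm{ICT}$); and a thigh-cuff
pulse whose foot sits exactly at $t_R + \mathrm{ICT} + d/v$. Morphology is
deliberately schematic — no wave reflections, cuff inflation dynamics,
respiration or arrhythmia — because the synthesis contract is fiducial
timing, not clinical realism. Beat intervals are $60/\mathrm{HR}$ with 3%
multiplicative jitter; defaults are 1000 Hz, 30 s, 2% white noise per
channel, with optional baseline wander off by default.

One geometric choice matters. The pulse-foot detector uses the
intersecting-tangents convention (the transit-time standard): the foot is
the crossing of the pre-upstroke baseline with the tangent through the point
of maximum upstroke slope. For a pure raised-cosine upstroke of rise time
$T_r$ this construction is *biased late by* $(1/2 - 1/\pi)\,T_r \approx
0.18\,T_r$ — about 15 ms at $T_r$ = 80 ms, which would corrupt measured PWV
by ≈ 7%. The synthesized upstroke therefore rises *linearly* through its
first 40% of amplitude before a raised-cosine completes the rise: the linear
launch carries the maximum slope, making the tangent construction exact at
the true foot. With this morphology the whole chain — synthesis, detection,
corrected PAT, division — recovers true PWV to within 1% on clean signals,
which is the round-trip property the test suite asserts.

Detector parameters are configuration, not magic: R-peaks use an adaptive
threshold (median + 6·MAD with a range-based floor for noise-free signals)
and a 0.3 s refractory period, refined by parabolic interpolation; valve
opening is the first crossing of 10% of the window's peak envelope,
backward-extrapolated to baseline; the foot tangent is fitted by least
squares over the region where the smoothed derivative exceeds 90% of its
window maximum. The derivative is estimated by a ±4 ms central difference
and then smoothed — a single-sample difference is far too noisy to anchor a
tangent. Individual windows without a credible upstroke (amplitude below 6
baseline MADs) are flagged and excluded rather than fatal; subject-level PWV
averages valid beats only (median available behind a flag). A
second-derivative-maximum foot definition is available
(`foot_method = "second_derivative"`) for sensitivity analyses.

## Statistics

* `quadratic_model()` fits OLS of an outcome on age, age², and optionally
  MAP, sex, BMI. Standardized betas are computed on z-scored variables with
  the *fitted* age polynomial $\hat c_1 a + \hat c_2 a^2$ treated as one
  composite predictor, so "age" gets a single beta comparable to the
  covariates' — the convention that reproduces a single reported age beta
  from a quadratic model. In athlete-preset simulations the composite age
  beta averages 0.93 and the MAP beta ≈ 0.12, with sex and BMI at zero.
* `bland_altman()` reports mean ± SD of the estimated−measured differences,
  limits of agreement at ±1.96 SD, the regression of the difference on age
  (the age trend of the bias), and the age-adjusted partial correlation.
* `partial_correlation_given_age()` residualizes both variables on
  {age, age²} and correlates the residuals; the p-value uses a t reference
  with $n-4$ degrees of freedom. Adjusting via partial correlation or via
  covariate regression is equivalent here; the package implements the former
  and the tests exploit the equivalence.
* `ks_normality()` tests against a normal with estimated parameters, using
  the Lilliefors correction by default (plain one-sample KS, which is
  conservative when parameters are estimated, behind a flag).
* Two-sided p-values throughout; no multiple-testing correction is applied,
  matching ordinary practice for a small descriptive analysis.

## The analytic oracle

`variance_decomposition_oracle()` computes, in closed form, what the
simulations should produce: cohort expectations of estimated and measured
PWV, their difference, and the population $R^2$ of estimated-vs-age,
measured-vs-age and estimated-vs-measured. Writing
$q(a) = (c_1 + 0.35\,c_3)\,a + c_2 a^2$ for the full age dependence of the
estimate (direct plus MAP trend), all variances and covariances reduce to
age moments; these are evaluated with *exact* truncated-normal raw moments
(via the standard recursion for truncated standard-normal moments,
`truncnorm_moments()`) rather than plain-normal identities, because with a
non-trivial age clip the latter are off by several percent. The test suite
requires pooled Monte-Carlo simulations of $10^5$ subjects to agree with the
oracle within 0.02 on every $R^2$ and 0.05 m/s on every mean — a dual-route
check in which the oracle never touches the simulation code path.

One subtlety in comparing simulated cohorts with published values: the
published $R^2$ come from single cohorts of n = 24 or 129, and the sample
$R^2$ of a small cohort is biased upward relative to the population value
(by roughly $p(1-\rho^2)/n$). The replicate-cohort analyses in the tests and
the acceptance script therefore average *per-cohort* sample $R^2$ at the
published cohort sizes, which is the quantity actually comparable to a
published single-cohort $R^2$.

## Problem sizes and determinism

The calibration-recovery analyses use 200 replicate cohorts per preset.
Bedrest-preset cohorts run the full signal pipeline at 12 s per recording
and 500 Hz with 2% noise — at least ten beats per subject, comfortably inside
the detectors' validated operating range, and enough beat-averaging that
detection noise contributes < 0.001 (m/s)² to the measured-PWV variance.
Athlete-preset replicates exercise the estimation protocol, which involves
no signals. The entered-age experiment is repeated over 50 seeds and
summarized by its median $R^2$. All analyses are deterministic given the
master seed.

## Known limitations

* The surrogate is a calibration device, not a reconstruction of any
  vendor's algorithm; only cohort-level statistics, not individual outputs,
  are meaningful.
* Waveform morphology is schematic; detector performance figures here do not
  transfer to clinical signals with reflections, arrhythmia or motion
  artefact, and no such claim is made.
* True PWV is modelled as linear in age with homoscedastic noise; real
  stiffness–age relations steepen at older ages.
* The generator treats blood pressure as one per-subject value; within-visit
  BP variability is folded into the device noise terms.
* Published per-subject data for the motivating cohorts are access-restricted,
  so agreement is asserted against published summary statistics, never
  against individual measurements.
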