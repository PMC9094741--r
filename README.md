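# pwvagree

Agreement between *estimated* and *transit-time measured* pulse wave velocity.

Aortic pulse wave velocity (PWV, m/s) is the reference measure of arterial
stiffness and an independent predictor of cardiovascular risk. Single-cuff
oscillometric monitors make it temptingly easy to obtain an "estimated PWV"
(ePWV) — but that estimate is, in essence, a deterministic function of the
age typed into the device and of brachial blood pressure. When such a device
is used on a cohort whose vessels are healthier (or stiffer) than their age
suggests — lifelong master athletes, say — the estimate tracks the entered
age, not the arteries.

`pwvagree` is a simulation-and-analysis package for studying exactly this
failure mode. It provides:

* a **calibrated cohort generator** (`draw_cohort()`) with two shipped
  presets: a master-athlete cohort (n = 129, age 56 ± 11) and a bedrest-study
  baseline cohort (n = 24, age 33 ± 9). True aortic PWV follows
  `v(a) = 3.48 + 0.04·a + ε`, `ε ~ N(0, 0.33²)` m/s; the device surrogate is
  the quadratic `f(a, MAP) = 5.87 − 0.0656·a + 0.001835·a² + 0.028·(MAP − 90)`
  in entered age `a` and mean arterial pressure, moment-matched so cohort
  expectations reproduce the published means (5.8 and 8.3 m/s);
* a **multichannel waveform synthesizer** (`synthesize_recording()`): ECG,
  Doppler ejection envelope and thigh-cuff pulse, with exact ground-truth
  annotations of each R-peak, aortic valve opening and pulse foot;
* **fiducial detectors** (`detect_fiducials()`): adaptive-threshold R-peak
  detection, 10%-threshold valve-opening onset, and the intersecting-tangents
  pulse-foot convention;
* the **transit-time PWV pipeline** (`compute_pwv()`): pulse arrival time
  (R-peak → cuff foot) corrected for isovolumetric contraction time
  (R-peak → valve opening), divided into the jugulum-to-thigh-cuff distance:
  `measured PWV = distance / (PAT − ICT)`;
* the **triplicate estimation protocol** (`estimate_pwv_protocol()`) and the
  single-subject **entered-age experiment** (`entered_age_experiment()`),
  where only the age typed into the device is varied (30–80 in decades,
  three readings each);
* the **statistics of method agreement**: quadratic regressions with
  standardized betas (`quadratic_model()`, with the fitted age polynomial as
  one composite predictor), age-alone R² (`r_squared_age_alone()`),
  Bland–Altman analysis with an age trend of the bias (`bland_altman()`),
  age-adjusted partial correlation (`partial_correlation_given_age()`),
  Lilliefors/KS normality checks (`ks_normality()`), and a closed-form
  variance-decomposition oracle (`variance_decomposition_oracle()`) used to
  validate the simulations analytically.

Everything is tibble-in / tibble-out and chains with the pipe; fitted objects
support `tidy()`, `glance()` and `autoplot()`.

## Worked example

```r
library(pwvagree)

cfg <- study_config(seed = 42, duration = 12, sampling_rate = 500)
study <- run_full_study(cfg)
study
#> <pwv_study>
#>   cohorts:
#>     athletes   n = 129  estimated 8.50 +/- 1.61 m/s
#>     agbresa    n =  24  estimated 5.91 +/- 0.65 m/s, measured 4.78 +/- 0.46 m/s
#>   regressions (R^2):
#>     athletes_estimated_full      0.994
#>     athletes_estimated_age       0.983
#>     agbresa_estimated_full       0.983
#>     agbresa_estimated_age        0.940
#>     agbresa_measured_age         0.441
#>     agbresa_difference_age       0.440
#>   agreement: mean difference 1.12 +/- 0.53 m/s, partial r | age = -0.127 (p = 0.575)
#>   entered-age experiment: R^2 = 0.9984
#>   seed: 42
```

Reading this: estimated PWV is almost entirely explained by age in *both*
cohorts (R² ≈ 0.98 in athletes, ≈ 0.94 in the bedrest cohort), while the
transit-time measured PWV relates to age far more loosely (R² ≈ 0.44 in this
single draw). The device overestimates the measured value by ≈ 1.1 m/s on
average, the bias grows with age, and once age is adjusted for, the partial
correlation between the two methods is indistinguishable from zero (p = 0.58)
— the estimate adds nothing beyond the age that was typed in. The
single-subject entered-age experiment makes the mechanism explicit: varying
only the entered age reproduces an R² of 0.998 against "age".

`write_study_report(study, "results/")` serializes the report as JSON plus
per-cohort CSVs and the three headline figures (estimated PWV vs age across
cohorts; method difference vs age; the entered-age experiment).

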