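#' Mean arterial pressure from cuff pressures
#'
#' Standard single-cuff convention: diastolic pressure plus one third of pulse
#' pressure.
#'
#' @param sbp Systolic pressure, mmHg.
#' @param dbp Diastolic pressure, mmHg. Must satisfy `sbp > dbp > 0`.
#' @return Mean arterial pressure in mmHg, strictly between `dbp` and `sbp`.
#' @examples
#' map_from_cuff(125, 70)
#' map_from_cuff(128, 78)
#' @export
map_from_cuff <- function(sbp, dbp) {
  if (length(sbp) != length(dbp)) {
    pwv_abort("sbp and dbp must have equal length", "invalid_input")
  }
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) ||
    any(dbp <= 0) || any(sbp <= dbp)) {
    pwv_abort("cuff pressures must satisfy sbp > dbp > 0", "invalid_input")
  }
  dbp + (sbp - dbp) / 3
}

#' Default coefficients of the estimated-PWV device surrogate
#'
#' The deterministic core of the device surrogate is the quadratic
#' \deqn{f(a, m) = c_0 + c_1 a + c_2 a^2 + c_3 (m - 90)}
#' with `a` the entered age in years and `m` mean arterial pressure in mmHg.
#' The coefficients are moment-matched so that cohort expectations (including
#' the Jensen term \eqn{c_2 \sigma_a^2}) reproduce the calibration anchors:
#' 5.8 m/s in the bedrest cohort (age 33 +/- 9), 8.3 m/s in the athlete cohort
#' (age 56 +/- 11), and about 12.4 m/s for an entered age of 80 at MAP 90.
#' The vertex of the age quadratic sits at \eqn{-c_1/(2 c_2) \approx 17.9}
#' years, below the valid domain, so the surrogate is strictly increasing in
#' age for all valid inputs.
#'
#' @return Named numeric vector `c(c0, c1, c2, c3)`.
#' @export
surrogate_coefs <- function() {
  c(c0 = 5.87, c1 = -0.0656, c2 = 0.001835, c3 = 0.028)
}

#' Deterministic core of the estimated-PWV device surrogate
#'
#' Stands in for the proprietary single-cuff estimation algorithm, whose
#' output is, by design, an almost deterministic function of the age entered
#' into the device and of mean arterial pressure. No attempt is made to
#' reproduce the actual device transfer function; the surrogate is calibrated
#' only so that cohort-level statistics match (see [surrogate_coefs()]).
#'
#' @param entered_age Age typed into the device, years; valid range 18-100.
#' @param map Mean arterial pressure, mmHg; valid range 50-140.
#' @param coefs Surrogate coefficients, default [surrogate_coefs()].
#' @return Estimated PWV in m/s, strictly increasing in both arguments.
#' @examples
#' estimate_pwv_core(55, 90)
#' estimate_pwv_core(55, 91) - estimate_pwv_core(55, 90) # the MAP slope, 0.028
#' @export
estimate_pwv_core <- function(entered_age, map, coefs = surrogate_coefs()) {
  if (any(!is.finite(entered_age)) || any(entered_age < 18) || any(entered_age > 100)) {
    pwv_abort("entered_age must lie in [18, 100] years", "invalid_input")
  }
  if (any(!is.finite(map)) || any(map < 50) || any(map > 140)) {
    pwv_abort("map must lie in [50, 140] mmHg", "invalid_input")
  }
  coefs <- as.numeric(coefs)
  coefs[1] + coefs[2] * entered_age + coefs[3] * entered_age^2 +
    coefs[4] * (map - 90)
}

#' True aortic pulse wave velocity model
#'
#' Ground-truth aortic PWV is linear in age with additive normal noise:
#' \eqn{v(a) = b_0 + b_1 a + \epsilon}, \eqn{\epsilon \sim N(0, \sigma^2)},
#' with defaults \eqn{b_0 = 3.48}, \eqn{b_1 = 0.04} m/s per year and
#' \eqn{\sigma = 0.33} m/s, so the expectation at age 33 is 4.80 m/s and the
#' age dependence is deliberately much weaker than the device surrogate's.
#'
#' @param age Chronological age, years.
#' @param intercept,slope,sd Model constants (m/s, m/s per year, m/s).
#' @param noise If `FALSE`, return the noise-free conditional mean.
#' @param seed Optional RNG seed.
#' @return True PWV in m/s (truncated below at 1.5 m/s for physiological
#'   plausibility; at the default constants truncation is a > 5 sigma event).
#' @examples
#' true_pwv_model(33, noise = FALSE) # 4.80
#' @export
true_pwv_model <- function(age, intercept = 3.48, slope = 0.04, sd = 0.33,
                           noise = TRUE, seed = NULL) {
  if (any(!is.finite(age)) || any(age < 0)) {
    pwv_abort("age must be finite and non-negative", "invalid_input")
  }
  mu <- intercept + slope * age
  if (!noise || sd <= 0) {
    return(pmax(mu, 1.5))
  }
  with_seed(seed, rtruncnorm(length(age), mu, sd, lower = 1.5))
}

#' Simulate a cohort of subjects
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: ages from a truncated normal; mean arterial pressure with a
#' within-cohort age trend (`map_slope` mmHg/yr, residual SD `map_sd`),
#' anchored so the cohort MAP mean equals the preset's cuff-implied MAP;
#' systolic/diastolic pressures recovered from MAP and an independent pulse
#' pressure draw; true aortic PWV from [true_pwv_model()]; isovolumetric
#' contraction time and jugulum-to-thigh-cuff path length from truncated
#' normals. The entered age defaults to the chronological age rounded to
#' integer years, as typed into a device.
#'
#' @param preset A [pwv_preset()] (or preset name, resolved with defaults).
#' @param seed Optional integer seed; the same preset and seed always yield
#'   an identical cohort.
#' @return A tibble of class `pwv_cohort`, one row per subject, with columns
#'   `subject_id, age, entered_age, sex, bmi, sbp, dbp, map, heart_rate,
#'   true_pwv, ict, distance` and attributes `preset` and `seed`.
#' @examples
#' draw_cohort(pwv_preset("agbresa"), seed = 1)
#' @export
draw_cohort <- function(preset, seed = NULL) {
  if (is.character(preset)) preset <- pwv_preset(preset)
  preset <- validate_preset(preset)
  seed <- seed %||% preset$seed
  with_seed(seed, {
    n <- preset$n
    age <- rtruncnorm(
      n, preset$age_mean, preset$age_sd,
      preset$age_range[1], preset$age_range[2]
    )
    mu_age <- truncnorm_moments(
      preset$age_mean, preset$age_sd,
      preset$age_range[1], preset$age_range[2]
    )$mean
    map_anchor <- preset_map_mean(preset) - preset$map_slope * mu_age
    map <- map_anchor + preset$map_slope * age + stats::rnorm(n, 0, preset$map_sd)
    map <- pmin(pmax(map, 55), 135) # keep inside the surrogate's valid domain
    pp_mean <- preset$sbp_mean - preset$dbp_mean
    pp_sd <- sqrt(max(preset$sbp_sd^2 - preset$dbp_sd^2, 0))
    pp <- rtruncnorm(n, pp_mean, pp_sd, 20, 100)
    dbp <- map - pp / 3
    sbp <- map + 2 * pp / 3
    sex <- ifelse(stats::runif(n) < preset$sex_ratio, "male", "female")
    cohort <- tibble::tibble(
      subject_id = sprintf("%s_%03d", preset$name, seq_len(n)),
      age = age,
      entered_age = as.integer(round(age)),
      sex = sex,
      bmi = rtruncnorm(n, preset$bmi_mean, preset$bmi_sd, 15, 45),
      sbp = sbp,
      dbp = dbp,
      map = map,
      heart_rate = rtruncnorm(n, preset$hr_mean, preset$hr_sd, 40, 110),
      true_pwv = true_pwv_model(
        age,
        intercept = preset$pwv_intercept, slope = preset$pwv_slope,
        sd = preset$pwv_sd
      ),
      ict = rtruncnorm(n, preset$ict_mean, preset$ict_sd, preset$ict_min, preset$ict_max),
      distance = rtruncnorm(n, preset$distance_mean, preset$distance_sd, 0.8, 1.2)
    )
    validate_cohort(cohort, preset)
    structure(cohort,
      class = c("pwv_cohort", class(cohort)),
      preset = preset, seed = seed
    )
  })
}

validate_cohort <- function(cohort, preset = NULL) {
  stopifnot(is.data.frame(cohort))
  if (anyDuplicated(cohort$subject_id)) {
    pwv_abort("subject_id values must be unique", "invalid_input")
  }
  with(cohort, {
    ok <- all(sbp > dbp) && all(dbp > 0) &&
      all(dbp < map & map < sbp) &&
      all(true_pwv > 0) &&
      all(ict >= 0.02 & ict <= 0.15) &&
      all(distance >= 0.5 & distance <= 1.5)
    if (!ok) pwv_abort("cohort violates subject invariants", "invalid_input")
  })
  if (!is.null(preset)) {
    if (nrow(cohort) != preset$n) {
      pwv_abort("cohort row count does not match preset n", "invalid_input")
    }
    if (any(cohort$age < preset$age_range[1] - 1e-9) ||
      any(cohort$age > preset$age_range[2] + 1e-9)) {
      pwv_abort("ages fall outside the preset age range", "invalid_input")
    }
  }
  invisible(cohort)
}
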