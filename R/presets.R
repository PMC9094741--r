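#' Cohort presets for the synthetic physiology generator
#'
#' A preset bundles the demographic and hemodynamic parameters from which
#' [draw_cohort()] simulates subjects: age distribution (truncated normal),
#' brachial blood pressure, BMI, sex ratio, heart rate, and the calibrated
#' model constants used for true aortic PWV, the mean-arterial-pressure age
#' trend, and the estimated-PWV device surrogate.
#'
#' Two calibrated presets are shipped:
#' \describe{
#'   \item{`athletes`}{129 master athletes, age 56 +/- 11 years (clip 35-86),
#'     BP 128 +/- 15 / 78 +/- 8 mmHg, BMI 24.0 +/- 3.5, 88/129 male,
#'     heart rate 61 +/- 11 bpm.}
#'   \item{`agbresa`}{24 healthy bedrest-study volunteers at baseline,
#'     age 33 +/- 9 years (wide adult clip 18-70 so the nominal age SD is
#'     preserved after truncation), BP 125 +/- 11 / 70 +/- 7 mmHg,
#'     BMI 24.3 +/- 2.1, 16/24 male, heart rate 62 +/- 9 bpm.}
#'   \item{`single_subject`}{one fixed man in his 50s with normal BMI and a
#'     fixed mean arterial pressure; used by the entered-age experiment.}
#' }
#'
#' The model constants are part of the preset so alternative calibrations can
#' be explored without touching code: `pwv_intercept`, `pwv_slope`, `pwv_sd`
#' parameterize true aortic PWV as a linear function of age plus noise;
#' `map_slope` and `map_sd` give mean arterial pressure a within-cohort age
#' trend (the intercept is anchored so the cohort MAP mean equals the value
#' implied by the preset's cuff pressures); `est_coefs` are the quadratic
#' age + MAP surrogate coefficients (see [estimate_pwv_core()]); `sigma_b` and
#' `sigma_r` are the between-subject and per-repetition SDs of the estimation
#' protocol, in m/s.
#'
#' @param preset Preset name: `"athletes"`, `"agbresa"`, `"single_subject"`,
#'   or `"custom"` (which requires all fields via `...`).
#' @param ... Named overrides for any preset field (e.g. `n`, `age_mean`).
#'
#' @return An object of class `pwv_preset` (a named list).
#' @seealso [draw_cohort()], [read_preset()], [variance_decomposition_oracle()]
#' @examples
#' pwv_preset("agbresa")
#' pwv_preset("athletes", n = 20)
#' @export
pwv_preset <- function(preset = c("athletes", "agbresa", "single_subject", "custom"),
                       ...) {
  name <- match.arg(preset)
  base <- list(
    name = name,
    n = 1L,
    age_mean = 50, age_sd = 10, age_range = c(18, 90),
    sbp_mean = 120, sbp_sd = 12, dbp_mean = 75, dbp_sd = 8,
    bmi_mean = 24, bmi_sd = 3, sex_ratio = 0.5,
    hr_mean = 60, hr_sd = 10,
    map_slope = 0.35, map_sd = 6,
    ict_mean = 0.06, ict_sd = 0.01, ict_min = 0.03, ict_max = 0.12,
    distance_mean = 1.00, distance_sd = 0.05,
    pwv_intercept = 3.48, pwv_slope = 0.04, pwv_sd = 0.33,
    est_coefs = surrogate_coefs(),
    sigma_b = 0.10, sigma_r = 0.10,
    seed = NULL
  )
  known <- switch(name,
    athletes = list(
      n = 129L, age_mean = 56, age_sd = 11, age_range = c(35, 86),
      sbp_mean = 128, sbp_sd = 15, dbp_mean = 78, dbp_sd = 8,
      bmi_mean = 24.0, bmi_sd = 3.5, sex_ratio = 88 / 129,
      hr_mean = 61, hr_sd = 11
    ),
    agbresa = list(
      n = 24L, age_mean = 33, age_sd = 9, age_range = c(18, 70),
      sbp_mean = 125, sbp_sd = 11, dbp_mean = 70, dbp_sd = 7,
      bmi_mean = 24.3, bmi_sd = 2.1, sex_ratio = 16 / 24,
      hr_mean = 62, hr_sd = 9
    ),
    single_subject = list(
      n = 1L, age_mean = 55, age_sd = 0, age_range = c(55, 55),
      sbp_mean = 125, sbp_sd = 0, dbp_mean = 70, dbp_sd = 0,
      bmi_mean = 24, bmi_sd = 0, sex_ratio = 1,
      hr_mean = 60, hr_sd = 0, map_sd = 0
    ),
    custom = list()
  )
  preset <- utils::modifyList(base, known)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(preset))
    if (length(bad)) {
      pwv_abort(
        paste0("unknown preset field(s): ", paste(bad, collapse = ", ")),
        "config_error"
      )
    }
    preset <- utils::modifyList(preset, dots)
  }
  preset <- validate_preset(preset)
  structure(preset, class = "pwv_preset")
}

#' @export
print.pwv_preset <- function(x, ...) {
  cat(sprintf(
    "<pwv_preset: %s>  n = %d, age %g +/- %g yr (clip %g-%g), BP %g/%g mmHg\n",
    x$name, x$n, x$age_mean, x$age_sd, x$age_range[1], x$age_range[2],
    x$sbp_mean, x$dbp_mean
  ))
  invisible(x)
}

validate_preset <- function(preset) {
  need <- c(
    "name", "n", "age_mean", "age_sd", "age_range", "sbp_mean", "sbp_sd",
    "dbp_mean", "dbp_sd", "bmi_mean", "bmi_sd", "sex_ratio", "hr_mean", "hr_sd"
  )
  missing <- setdiff(need, names(preset))
  if (length(missing)) {
    pwv_abort(
      paste0("preset is missing field(s): ", paste(missing, collapse = ", ")),
      "config_error"
    )
  }
  if (!is.numeric(preset$n) || length(preset$n) != 1 || preset$n < 1) {
    pwv_abort("preset n must be a single count >= 1", "config_error")
  }
  preset$n <- as.integer(preset$n)
  sds <- c(
    preset$age_sd, preset$sbp_sd, preset$dbp_sd, preset$bmi_sd,
    preset$hr_sd, preset$map_sd, preset$ict_sd, preset$distance_sd,
    preset$pwv_sd, preset$sigma_b, preset$sigma_r
  )
  if (any(sds < 0)) {
    pwv_abort("all preset standard deviations must be >= 0", "config_error")
  }
  if (length(preset$age_range) != 2 || preset$age_range[1] > preset$age_range[2]) {
    pwv_abort("age_range must be [min, max] with min <= max", "config_error")
  }
  if (preset$sex_ratio < 0 || preset$sex_ratio > 1) {
    pwv_abort("sex_ratio must be a fraction in [0, 1]", "config_error")
  }
  if (preset$sbp_mean <= preset$dbp_mean) {
    pwv_abort("preset sbp_mean must exceed dbp_mean", "config_error")
  }
  preset
}

# Cohort-mean MAP implied by the preset's cuff pressures.
preset_map_mean <- function(preset) {
  preset$dbp_mean + (preset$sbp_mean - preset$dbp_mean) / 3
}

#' Read a cohort preset from a YAML configuration file
#'
#' Presets are plain key-value YAML documents; any field of [pwv_preset()] may
#' be given. A `name` key selecting one of the shipped presets supplies
#' defaults for fields not present in the file. The packaged defaults live at
#' `system.file("extdata", "presets.yaml", package = "pwvagree")`, one document
#' per preset keyed by preset name.
#'
#' @param path Path to a YAML file describing one preset.
#' @param which For a multi-preset file (a top-level mapping of preset names),
#'   the entry to extract; ignored for single-preset files.
#' @return A `pwv_preset`.
#' @export
read_preset <- function(path, which = NULL) {
  if (!file.exists(path)) {
    pwv_abort(paste0("preset file not found: ", path), "config_error")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(which)) {
    if (is.null(raw[[which]])) {
      pwv_abort(paste0("preset '", which, "' not found in ", path), "config_error")
    }
    raw <- raw[[which]]
    raw$name <- raw$name %||% which
  }
  name <- raw$name %||% "custom"
  raw$name <- NULL
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  if (!is.null(raw$age_range)) raw$age_range <- as.numeric(unlist(raw$age_range))
  if (!is.null(raw$est_coefs)) raw$est_coefs <- as.numeric(unlist(raw$est_coefs))
  do.call(pwv_preset, c(list(preset = name), raw))
}
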