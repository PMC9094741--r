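#' Study configuration
#'
#' Collects every knob of the one-shot study run: which presets to simulate,
#' which of them get the full signal pipeline (waveforms, fiducial detection,
#' measured PWV) in addition to the estimation protocol, the recording
#' settings, the entered-age grid, and the master seed from which all
#' randomness flows.
#'
#' @param presets Character vector of preset names to simulate.
#' @param measure Presets for which transit-time measured PWV is computed via
#'   the full signal pipeline (default `"agbresa"`).
#' @param seed Master integer seed.
#' @param duration,sampling_rate,noise_sd Recording settings for the signal
#'   pipeline.
#' @param entered_ages Entered-age grid for the single-subject experiment.
#' @param entered_age_reps Measurements per entered age.
#' @param n_replicates Replicate cohorts per preset (default 1; replicate `k`
#'   uses a seed derived from the master seed).
#' @param overrides Named list of per-preset field overrides, e.g.
#'   `list(agbresa = list(n = 12))`.
#' @return A validated list of class `pwv_study_config`.
#' @export
study_config <- function(presets = c("athletes", "agbresa"),
                         measure = "agbresa",
                         seed = 42L,
                         duration = 30, sampling_rate = 1000, noise_sd = 0.02,
                         entered_ages = seq(30, 80, by = 10),
                         entered_age_reps = 3L,
                         n_replicates = 1L,
                         overrides = list()) {
  config <- list(
    presets = presets, measure = measure, seed = as.integer(seed),
    duration = duration, sampling_rate = sampling_rate, noise_sd = noise_sd,
    entered_ages = entered_ages, entered_age_reps = entered_age_reps,
    n_replicates = as.integer(n_replicates), overrides = overrides
  )
  validate_study_config(config)
}

validate_study_config <- function(config) {
  if (!length(config$presets)) {
    pwv_abort("config must name at least one preset", "config_error")
  }
  if (config$n_replicates < 1) {
    pwv_abort("replicate count must be >= 1", "config_error")
  }
  bad <- setdiff(config$measure, config$presets)
  if (length(bad)) {
    pwv_abort(
      paste0("measure preset(s) not simulated: ", paste(bad, collapse = ", ")),
      "config_error"
    )
  }
  # resolve preset objects now so malformed presets fail before any simulation
  config$preset_objects <- lapply(config$presets, function(nm) {
    ov <- config$overrides[[nm]] %||% list()
    tryCatch(
      do.call(pwv_preset, c(list(preset = nm), ov)),
      pwvagree_error = function(e) {
        pwv_abort(paste0("invalid preset '", nm, "': ", conditionMessage(e)),
          "config_error",
          parent = e
        )
      }
    )
  })
  names(config$preset_objects) <- config$presets
  structure(config, class = "pwv_study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [study_config()].
#' @return A `pwv_study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    pwv_abort(paste0("config file not found: ", path), "config_error")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    pwv_abort(
      paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
      "config_error"
    )
  }
  if (!is.null(raw$entered_ages)) raw$entered_ages <- as.numeric(unlist(raw$entered_ages))
  do.call(study_config, raw)
}

#' Run the full two-cohort comparison study
#'
#' Drives the whole pipeline in one call, mirroring the structure of the
#' method-comparison analysis: simulate each preset cohort; run the
#' triplicate estimation protocol everywhere; run the signal pipeline
#' (synthesis, fiducial detection, corrected PAT, measured PWV) for the
#' cohorts named in `config$measure`; fit the quadratic regressions
#' (full-covariate and age-alone, per cohort and outcome); perform the
#' Bland-Altman / partial-correlation agreement analysis between methods; run
#' the single-subject entered-age experiment; and test all primary outcomes
#' for normality. Identical configurations (including seed) give identical
#' reports.
#'
#' @param config A [study_config()] (default settings if omitted).
#' @return An object of class `pwv_study`: list with `cohort_summaries`,
#'   `records` (named list of per-preset tibbles), `regressions` (named list
#'   of [quadratic_model()] fits), `agreement` ([bland_altman()]),
#'   `entered_age` ([entered_age_experiment()]), `normality`, and `provenance`
#'   (seed, package version, config hash).
#' @examples
#' \donttest{
#' cfg <- study_config(
#'   seed = 7, duration = 10, sampling_rate = 500,
#'   overrides = list(athletes = list(n = 30), agbresa = list(n = 12))
#' )
#' run_full_study(cfg)
#' }
#' @export
run_full_study <- function(config = study_config()) {
  if (!inherits(config, "pwv_study_config")) {
    config <- validate_study_config(config)
  }
  records <- list()
  for (k in seq_along(config$presets)) {
    nm <- config$presets[k]
    preset <- config$preset_objects[[nm]]
    reps <- purrr::map(seq_len(config$n_replicates), function(r) {
      seed_k <- derive_seed(config$seed, 1000L * k + r)
      cohort <- draw_cohort(preset, seed = seed_k)
      if (nm %in% config$measure) {
        rec <- compute_pwv(
          cohort,
          duration = config$duration,
          sampling_rate = config$sampling_rate,
          noise_sd = config$noise_sd,
          seed = derive_seed(seed_k, 1L)
        )
      } else {
        rec <- estimate_pwv_protocol(cohort, seed = derive_seed(seed_k, 2L))
      }
      rec$replicate <- r
      rec
    })
    records[[nm]] <- dplyr::bind_rows(reps)
  }

  cohort_summaries <- purrr::imap_dfr(records, function(rec, nm) {
    tibble::tibble(
      preset = nm,
      n = nrow(rec),
      estimated_mean = mean(rec$estimated_pwv),
      estimated_sd = stats::sd(rec$estimated_pwv),
      measured_mean = if ("measured_pwv" %in% names(rec)) mean(rec$measured_pwv) else NA_real_,
      measured_sd = if ("measured_pwv" %in% names(rec)) stats::sd(rec$measured_pwv) else NA_real_
    )
  })

  regressions <- list()
  for (nm in names(records)) {
    rec <- records[[nm]]
    regressions[[paste0(nm, "_estimated_full")]] <-
      quadratic_model(rec, "estimated_pwv")
    regressions[[paste0(nm, "_estimated_age")]] <-
      quadratic_model(rec, "estimated_pwv", covariates = NULL)
    if ("measured_pwv" %in% names(rec)) {
      regressions[[paste0(nm, "_measured_age")]] <-
        quadratic_model(rec, "measured_pwv", covariates = NULL)
      rec$method_difference <- rec$estimated_pwv - rec$measured_pwv
      regressions[[paste0(nm, "_difference_age")]] <-
        quadratic_model(rec, "method_difference", covariates = NULL)
    }
  }

  measured_sets <- Filter(function(r) "measured_pwv" %in% names(r), records)
  agreement <- if (length(measured_sets)) {
    bland_altman(measured_sets[[1]])
  } else {
    NULL
  }

  entered_age <- entered_age_experiment(
    ages = config$entered_ages,
    reps = config$entered_age_reps,
    seed = derive_seed(config$seed, 99L)
  )

  normality <- purrr::imap_dfr(records, function(rec, nm) {
    vars <- intersect(c("estimated_pwv", "measured_pwv"), names(rec))
    purrr::map_dfr(vars, function(v) {
      dplyr::mutate(ks_normality(rec[[v]]), preset = nm, variable = v, .before = 1)
    })
  })

  structure(
    list(
      cohort_summaries = cohort_summaries,
      records = records,
      regressions = regressions,
      agreement = agreement,
      entered_age = entered_age,
      normality = normality,
      provenance = list(
        seed = config$seed,
        package_version = as.character(utils::packageVersion("pwvagree")),
        config_hash = rlang::hash(config[setdiff(names(config), "preset_objects")])
      )
    ),
    class = "pwv_study"
  )
}

#' @export
print.pwv_study <- function(x, ...) {
  cat("<pwv_study>\n")
  cat("  cohorts:\n")
  for (i in seq_len(nrow(x$cohort_summaries))) {
    s <- x$cohort_summaries[i, ]
    cat(sprintf(
      "    %-10s n = %3d  estimated %.2f +/- %.2f m/s%s\n",
      s$preset, s$n, s$estimated_mean, s$estimated_sd,
      if (is.na(s$measured_mean)) {
        ""
      } else {
        sprintf(", measured %.2f +/- %.2f m/s", s$measured_mean, s$measured_sd)
      }
    ))
  }
  cat("  regressions (R^2):\n")
  for (nm in names(x$regressions)) {
    cat(sprintf("    %-28s %.3f\n", nm, x$regressions[[nm]]$r_squared))
  }
  if (!is.null(x$agreement)) {
    cat(sprintf(
      "  agreement: mean difference %.2f +/- %.2f m/s, partial r | age = %.3f (p = %.3f)\n",
      x$agreement$mean_difference, x$agreement$sd_difference,
      x$agreement$partial_r_given_age, x$agreement$partial_p
    ))
  }
  cat(sprintf("  entered-age experiment: R^2 = %.4f\n", x$entered_age$r_squared))
  cat(sprintf("  seed: %d\n", x$provenance$seed))
  invisible(x)
}

study_report_list <- function(study) {
  reg <- lapply(study$regressions, function(m) {
    list(
      outcome = m$outcome,
      predictors = m$predictors,
      coefficients = as.list(m$coefficients),
      standardized = m$standardized,
      r_squared = m$r_squared,
      n = m$n
    )
  })
  agr <- if (is.null(study$agreement)) NULL else {
    a <- study$agreement
    list(
      mean_difference = a$mean_difference,
      sd_difference = a$sd_difference,
      limits_of_agreement = as.list(a$limits_of_agreement),
      diff_vs_age_slope = a$diff_vs_age_slope,
      diff_vs_age_r_squared = a$diff_vs_age_r_squared,
      diff_vs_age_p = a$diff_vs_age_p,
      partial_r_given_age = a$partial_r_given_age,
      partial_p = a$partial_p,
      n = a$n
    )
  }
  list(
    cohort_summaries = study$cohort_summaries,
    regressions = reg,
    agreement = agr,
    entered_age = list(
      coefficients = as.list(study$entered_age$coefficients),
      r_squared = study$entered_age$r_squared,
      n = nrow(study$entered_age$measurements)
    ),
    normality = study$normality,
    provenance = study$provenance
  )
}

#' Serialize a study to disk
#'
#' Writes `report.json` with all summary statistics, one records CSV per
#' cohort (every reported number is recomputable from these), and, when
#' `figures = TRUE`, the three headline figures: estimated PWV vs age across
#' cohorts (`fig1a.png`), the method difference vs age (`fig1b.png`), and the
#' entered-age experiment (`fig1c.png`).
#'
#' @param study A `pwv_study` from [run_full_study()].
#' @param dir Output directory, created if needed.
#' @param figures Write PNG figures (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(study, dir, figures = TRUE) {
  stopifnot(inherits(study, "pwv_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(
    study_report_list(study),
    paths[1],
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  for (nm in names(study$records)) {
    p <- file.path(dir, paste0("records_", nm, ".csv"))
    readr::write_csv(study$records[[nm]], p)
    paths <- c(paths, p)
  }
  if (figures) {
    figs <- list(
      fig1a.png = plot_age_correlation(study),
      fig1b.png = if (!is.null(study$agreement)) ggplot2::autoplot(study$agreement) else NULL,
      fig1c.png = ggplot2::autoplot(study$entered_age)
    )
    for (nm in names(figs)) {
      if (is.null(figs[[nm]])) next
      p <- file.path(dir, nm)
      grDevices::png(p, width = 1200, height = 900, res = 150)
      print(figs[[nm]])
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
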