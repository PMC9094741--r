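#' Corrected pulse arrival time from detected fiducials
#'
#' Pulse arrival time (PAT, R-peak to cuff foot) contains the isovolumetric
#' contraction time (ICT, R-peak to aortic valve opening), during which no
#' pulse travels. Subtracting the mean detected ICT from the mean detected PAT
#' gives the corrected PAT: the travel time from valve opening to the thigh
#' cuff. Only beats flagged valid contribute.
#'
#' @param fiducials A `pwv_fiducials` table (see [detect_fiducials()]).
#' @param aggregate Per-beat aggregator, `"mean"` (default) or `"median"`.
#' @return A one-row tibble with `n_beats`, `pat`, `ict_hat`, `cpat` (seconds).
#' @export
corrected_pat <- function(fiducials, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  ok <- fiducials[fiducials$valid, , drop = FALSE]
  if (nrow(ok) < 3) {
    pwv_abort("fewer than 3 valid beats", "insufficient_signal")
  }
  pat <- agg(ok$t_foot_hat - ok$t_r_hat)
  ict_hat <- agg(ok$t_valve_hat - ok$t_r_hat)
  cpat <- pat - ict_hat
  if (!is.finite(cpat) || cpat <= 0) {
    pwv_abort("corrected PAT is not positive (ICT >= PAT)", "implausible_timing")
  }
  tibble::tibble(n_beats = nrow(ok), pat = pat, ict_hat = ict_hat, cpat = cpat)
}

#' Measured pulse wave velocity
#'
#' Path length (jugulum to thigh cuff) divided by the corrected pulse arrival
#' time.
#'
#' @param distance Path length in metres.
#' @param cpat Corrected pulse arrival time in seconds.
#' @return PWV in m/s.
#' @examples
#' measured_pwv(1.0, 0.20) # 5 m/s
#' @export
measured_pwv <- function(distance, cpat) {
  if (any(!is.finite(distance)) || any(!is.finite(cpat)) ||
    any(distance <= 0) || any(cpat <= 0)) {
    pwv_abort("distance and cpat must be positive", "invalid_input")
  }
  distance / cpat
}

#' Triplicate estimated-PWV protocol
#'
#' Emulates the clinical protocol of acquiring the device's PWV estimate three
#' times per subject after supine rest. Each repetition is the deterministic
#' surrogate core [estimate_pwv_core()] evaluated at the subject's entered age
#' and MAP, plus a per-subject deviation `b ~ N(0, sigma_b^2)` (drawn once per
#' subject: the device's reproducible offset for that person) and independent
#' per-repetition noise `e_i ~ N(0, sigma_r^2)`. The reported estimate is the
#' mean of the three repetitions, so its variance around the core is
#' `sigma_b^2 + sigma_r^2 / 3`.
#'
#' @param cohort A `pwv_cohort` (or any data frame with `entered_age`, `map`).
#' @param sigma_b Between-subject deviation SD, m/s (default 0.10).
#' @param sigma_r Per-repetition noise SD, m/s (default 0.10).
#' @param reps Number of repetitions (default 3).
#' @param coefs Surrogate coefficients, default [surrogate_coefs()].
#' @param seed Optional RNG seed.
#' @return The input tibble with added columns `est_rep1 ... est_repK` and
#'   `estimated_pwv` (their mean).
#' @examples
#' draw_cohort("agbresa", seed = 1) |> estimate_pwv_protocol(seed = 2)
#' @export
estimate_pwv_protocol <- function(cohort, sigma_b = 0.10, sigma_r = 0.10,
                                  reps = 3L, coefs = surrogate_coefs(),
                                  seed = NULL) {
  stopifnot(is.data.frame(cohort), reps >= 1)
  core <- estimate_pwv_core(cohort$entered_age, cohort$map, coefs = coefs)
  n <- nrow(cohort)
  with_seed(seed, {
    b <- if (sigma_b > 0) stats::rnorm(n, 0, sigma_b) else numeric(n)
    rep_mat <- sapply(seq_len(reps), function(i) {
      core + b + if (sigma_r > 0) stats::rnorm(n, 0, sigma_r) else 0
    })
    rep_mat <- matrix(rep_mat, nrow = n)
    out <- cohort
    for (i in seq_len(reps)) out[[paste0("est_rep", i)]] <- rep_mat[, i]
    out$estimated_pwv <- rowMeans(rep_mat)
    out
  })
}

#' Full per-subject PWV pipeline
#'
#' For each subject of a cohort: synthesize the multichannel recording,
#' detect fiducials (without looking at the truth annotations), compute the
#' corrected pulse arrival time and measured PWV, and run the triplicate
#' estimation protocol. This is the simulated analogue of the two-method
#' comparison study: per subject, one transit-time measured PWV and one
#' device-estimated PWV.
#'
#' @param cohort A `pwv_cohort`.
#' @param duration,sampling_rate,noise_sd Recording settings, see
#'   [synthesize_recording()].
#' @param seed Optional seed; per-subject signal seeds are derived from it.
#' @param aggregate Beat aggregation for [corrected_pat()].
#' @param ... Further arguments passed to [detect_fiducials()].
#' @return A tibble of class `pwv_records` with one row per subject:
#'   demographics plus `n_beats`, `pat`, `ict_hat`, `cpat`, `measured_pwv`,
#'   `est_rep1..3`, `estimated_pwv`.
#' @examples
#' \donttest{
#' cohort <- draw_cohort("agbresa", seed = 1)
#' compute_pwv(cohort[1:3, ], duration = 10, sampling_rate = 500, seed = 1)
#' }
#' @export
compute_pwv <- function(cohort, duration = 30, sampling_rate = 1000,
                        noise_sd = 0.02, seed = NULL,
                        aggregate = c("mean", "median"), ...) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1)
  timing <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    subject <- cohort[i, , drop = FALSE]
    tryCatch(
      {
        bundle <- synthesize_recording(
          subject,
          duration = duration, sampling_rate = sampling_rate,
          noise_sd = noise_sd, seed = derive_seed(seed, i)
        )
        fid <- detect_fiducials(bundle, ...)
        cp <- corrected_pat(fid, aggregate = aggregate)
        cp$measured_pwv <- measured_pwv(subject$distance, cp$cpat)
        cp
      },
      pwvagree_error = function(e) {
        pwv_abort(
          paste0(
            "PWV pipeline failed for subject ", subject$subject_id,
            ": ", conditionMessage(e)
          ),
          "stage_error",
          parent = e
        )
      }
    )
  })
  records <- dplyr::bind_cols(tibble::as_tibble(cohort), timing)
  records <- estimate_pwv_protocol(records, seed = derive_seed(seed, 500009L))
  structure(records, class = c("pwv_records", class(records)))
}

#' Entered-age experiment
#'
#' Holds one subject (and hence their blood pressure and per-subject device
#' deviation) fixed while the age *entered into the device* is varied in
#' decades, in random order, with several estimate repetitions per entered
#' age. A quadratic of estimated PWV on entered age is then fitted. Because
#' the surrogate core is a deterministic quadratic in entered age, the fit's
#' R-squared is limited only by the per-repetition noise, which is how a
#' single subject can display near-perfect "age dependence" of their vascular
#' stiffness estimate.
#'
#' @param subject One-row data frame with `map` (and optionally `subject_id`);
#'   defaults to the `single_subject` preset's fixed man in his 50s.
#' @param ages Grid of entered ages, default `seq(30, 80, 10)`; at least 3
#'   distinct values.
#' @param reps Measurements per entered age (default 3).
#' @param sigma_r Per-repetition noise SD, m/s.
#' @param subject_bias The subject's fixed device deviation `b`, m/s
#'   (default 0; it is constant across entries so it never affects the fit's
#'   R-squared).
#' @param coefs Surrogate coefficients.
#' @param seed Optional RNG seed (controls entry order and repetition noise).
#' @return An object of class `entered_age_result`: list with `measurements`
#'   (tibble `order, entered_age, rep, value`), `fit` (the quadratic `lm`),
#'   `coefficients`, `r_squared`, `subject_id`.
#' @examples
#' entered_age_experiment(seed = 7)
#' @export
entered_age_experiment <- function(subject = NULL, ages = seq(30, 80, by = 10),
                                   reps = 3L, sigma_r = 0.10, subject_bias = 0,
                                   coefs = surrogate_coefs(), seed = NULL) {
  if (is.null(subject)) {
    subject <- draw_cohort(pwv_preset("single_subject"), seed = 0L)
  }
  subject <- subject[1, , drop = FALSE]
  ages <- unique(as.numeric(ages))
  if (length(ages) < 3) {
    pwv_abort("need at least 3 distinct entered ages", "invalid_input")
  }
  if (reps < 1) pwv_abort("reps must be >= 1", "invalid_input")
  with_seed(seed, {
    order_idx <- sample(length(ages)) # ages are entered in random order
    grid <- tibble::tibble(
      order = rep(seq_along(ages), each = reps),
      entered_age = rep(ages[order_idx], each = reps),
      rep = rep(seq_len(reps), times = length(ages))
    )
    core <- estimate_pwv_core(grid$entered_age, subject$map, coefs = coefs)
    noise <- if (sigma_r > 0) stats::rnorm(nrow(grid), 0, sigma_r) else 0
    grid$value <- core + subject_bias + noise
    fit <- stats::lm(value ~ entered_age + I(entered_age^2), data = grid)
    structure(
      list(
        measurements = grid,
        fit = fit,
        coefficients = stats::coef(fit),
        r_squared = summary(fit)$r.squared,
        subject_id = as.character(subject$subject_id %||% "subject")
      ),
      class = "entered_age_result"
    )
  })
}

#' @export
print.entered_age_result <- function(x, ...) {
  rng <- range(x$measurements$entered_age)
  cat(sprintf(
    "<entered_age_result: %s>  entered ages %g-%g, %d measurements, R^2 = %.4f\n",
    x$subject_id, rng[1], rng[2], nrow(x$measurements), x$r_squared
  ))
  invisible(x)
}
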