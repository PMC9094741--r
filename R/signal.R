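#' Ground-truth beat schedule for a subject
#'
#' Lays out R-peak times at intervals of `60/heart_rate` seconds with
#' multiplicative normal jitter, then places the aortic valve opening exactly
#' one isovolumetric contraction time (ICT) after each R-peak and the pulse
#' arrival at the thigh cuff exactly `distance / true_pwv` after the valve
#' opening. The schedule is the ground truth that waveform synthesis renders
#' and fiducial detection must recover.
#'
#' @param subject A one-row data frame with columns `heart_rate`, `ict`,
#'   `distance`, `true_pwv` (a [draw_cohort()] row works directly).
#' @param duration Recording length in seconds, at least 5.
#' @param jitter_sd SD of the multiplicative beat-interval jitter (default 3%).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `beat_index`, `t_r`, `t_valve`, `t_foot`
#'   (seconds), satisfying `t_valve - t_r == ict` and
#'   `t_foot - t_valve == distance / true_pwv` exactly.
#' @examples
#' s <- draw_cohort(pwv_preset("single_subject"), seed = 1)
#' beat_schedule(s, duration = 10, jitter_sd = 0, seed = 1)
#' @export
beat_schedule <- function(subject, duration = 30, jitter_sd = 0.03, seed = NULL) {
  subject <- as.list(subject[1, , drop = FALSE])
  if (!is.numeric(duration) || duration < 5) {
    pwv_abort("duration must be at least 5 seconds", "invalid_input")
  }
  for (f in c("heart_rate", "ict", "distance", "true_pwv")) {
    if (is.null(subject[[f]]) || !is.finite(subject[[f]]) || subject[[f]] <= 0) {
      pwv_abort(paste0("subject field '", f, "' must be a positive number"), "invalid_input")
    }
  }
  rr <- 60 / subject$heart_rate
  transit <- subject$distance / subject$true_pwv
  # Leave room after the last foot for the cuff upstroke (80 ms) plus slack.
  tail_pad <- 0.15
  with_seed(seed, {
    n_max <- ceiling(duration / (rr * 0.8)) + 2L
    jit <- if (jitter_sd > 0) pmax(stats::rnorm(n_max, 1, jitter_sd), 0.5) else rep(1, n_max)
    t_r <- 0.25 + cumsum(c(0, rr * jit))[seq_len(n_max)]
    t_r <- t_r[t_r + subject$ict + transit + tail_pad <= duration]
    if (length(t_r) < 3) {
      pwv_abort("recording too short for at least 3 beats", "insufficient_signal")
    }
    tibble::tibble(
      beat_index = seq_along(t_r),
      t_r = t_r,
      t_valve = t_r + subject$ict,
      t_foot = t_r + subject$ict + transit
    )
  })
}

# Raised-cosine upstroke with a linear launch: the first `launch` fraction of
# the amplitude rises linearly from the foot (slope launch/u0 per unit rise
# time), then a raised-cosine completes the rise. The linear segment carries
# the maximum slope, so the intersecting-tangents foot of this pulse is the
# true onset, exactly.
cuff_upstroke_shape <- function(u, launch = 0.4, u0 = 0.2) {
  s <- numeric(length(u))
  lin <- u > 0 & u <= u0
  cosr <- u > u0 & u <= 1
  s[lin] <- (launch / u0) * u[lin]
  s[cosr] <- launch + (1 - launch) / 2 * (1 - cos(pi * (u[cosr] - u0) / (1 - u0)))
  s[u > 1] <- 1
  s
}

#' Synthesize a multichannel recording for one subject
#'
#' Renders the subject's [beat_schedule()] into three uniformly sampled
#' channels mimicking the instruments of a transit-time PWV measurement:
#' \describe{
#'   \item{`ecg`}{narrow Gaussian QRS complexes (about 20 ms wide) centred on
#'     each R-peak over a flat baseline;}
#'   \item{`doppler_env`}{a half-sine ejection envelope starting exactly at
#'     each aortic valve opening;}
#'   \item{`cuff`}{a thigh-cuff pulse: flat baseline before each pulse foot,
#'     an ~80 ms upstroke whose leading edge is linear (so the
#'     intersecting-tangents foot definition is exact), then exponential
#'     decay.}
#' }
#' White noise with SD `noise_sd` times the unit channel amplitude is added to
#' every channel. Morphology is deliberately schematic: the synthesis contract
#' is the exact placement of fiducial times, not clinical realism.
#'
#' @inheritParams beat_schedule
#' @param sampling_rate Samples per second, at least 200 (default 1000).
#' @param noise_sd Additive white-noise SD as a fraction of channel amplitude.
#' @param baseline_wander If `TRUE`, add a slow 0.25 Hz sinusoidal drift to the
#'   cuff channel (off by default).
#' @param schedule Optionally, a precomputed [beat_schedule()] to render.
#' @return An object of class `waveform_bundle`: a list with `subject_id`,
#'   `sampling_rate`, `duration`, `channels` (tibble `t, ecg, doppler_env,
#'   cuff`) and `truth` (the beat schedule).
#' @examples
#' s <- draw_cohort(pwv_preset("single_subject"), seed = 1)
#' b <- synthesize_recording(s, duration = 8, sampling_rate = 500, seed = 2)
#' b
#' @export
synthesize_recording <- function(subject, duration = 30, sampling_rate = 1000,
                                 noise_sd = 0.02, jitter_sd = 0.03, seed = NULL,
                                 baseline_wander = FALSE, schedule = NULL) {
  if (!is.numeric(sampling_rate) || sampling_rate < 200) {
    pwv_abort("sampling_rate must be at least 200 Hz", "invalid_input")
  }
  subject_row <- subject[1, , drop = FALSE]
  with_seed(seed, {
    truth <- schedule %||%
      beat_schedule(subject_row, duration = duration, jitter_sd = jitter_sd)
    n <- round(duration * sampling_rate)
    t <- (seq_len(n) - 1) / sampling_rate
    ecg <- numeric(n)
    dopp <- numeric(n)
    cuff <- numeric(n)
    qrs_sd <- 0.008 # ~20 ms full width
    ejection <- 0.30 # half-sine burst length, s
    rise <- 0.08 # cuff upstroke duration, s
    decay_tau <- 0.12 # cuff diastolic decay constant, s
    for (b in seq_len(nrow(truth))) {
      tr <- truth$t_r[b]
      tv <- truth$t_valve[b]
      tf <- truth$t_foot[b]
      i <- which(t >= tr - 5 * qrs_sd & t <= tr + 5 * qrs_sd)
      ecg[i] <- ecg[i] + exp(-(t[i] - tr)^2 / (2 * qrs_sd^2))
      j <- which(t >= tv & t <= tv + ejection)
      dopp[j] <- dopp[j] + sin(pi * (t[j] - tv) / ejection)
      k <- which(t >= tf & t <= tf + rise)
      cuff[k] <- cuff[k] + cuff_upstroke_shape((t[k] - tf) / rise)
      # decay, truncated 60 ms before the next foot so every beat sees an
      # exactly flat pre-foot baseline
      decay_end <- if (b < nrow(truth)) truth$t_foot[b + 1] - 0.06 else tf + rise + 1.2
      l <- which(t > tf + rise & t <= min(tf + rise + 1.2, decay_end))
      cuff[l] <- cuff[l] + exp(-(t[l] - tf - rise) / decay_tau)
    }
    if (baseline_wander) {
      cuff <- cuff + 0.05 * sin(2 * pi * 0.25 * t)
    }
    if (noise_sd > 0) {
      ecg <- ecg + stats::rnorm(n, 0, noise_sd)
      dopp <- dopp + stats::rnorm(n, 0, noise_sd)
      cuff <- cuff + stats::rnorm(n, 0, noise_sd)
    }
    structure(
      list(
        subject_id = as.character(subject_row$subject_id %||% "subject"),
        sampling_rate = sampling_rate,
        duration = duration,
        channels = tibble::tibble(t = t, ecg = ecg, doppler_env = dopp, cuff = cuff),
        truth = truth
      ),
      class = "waveform_bundle"
    )
  })
}

#' @export
print.waveform_bundle <- function(x, ...) {
  cat(sprintf(
    "<waveform_bundle: %s>  %g s at %g Hz, %d beats, channels: %s\n",
    x$subject_id, x$duration, x$sampling_rate, nrow(x$truth),
    paste(setdiff(names(x$channels), "t"), collapse = ", ")
  ))
  invisible(x)
}
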