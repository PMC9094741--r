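#' Detect ECG R-peaks
#'
#' Local maxima above an adaptive robust threshold (median plus `k` times the
#' MAD, with a range-based floor so noise-free recordings are handled), kept
#' greedily by amplitude subject to a refractory period, and refined by
#' parabolic interpolation around the peak sample.
#'
#' @param ecg Numeric ECG samples.
#' @param sampling_rate Samples per second.
#' @param k Threshold multiplier on the MAD (default 6).
#' @param refractory Minimum separation between peaks, seconds (default 0.3).
#' @return Numeric vector of R-peak times in seconds (sample times start at 0).
#' @export
detect_r_peaks <- function(ecg, sampling_rate, k = 6, refractory = 0.3) {
  n <- length(ecg)
  if (n < 5 * sampling_rate) {
    pwv_abort("need at least 5 s of ECG signal", "invalid_input")
  }
  med <- stats::median(ecg)
  thr <- med + max(k * stats::mad(ecg), 0.25 * (max(ecg) - med))
  if (!is.finite(thr) || max(ecg) <= thr) {
    pwv_abort("fewer than 3 R-peaks found", "insufficient_signal")
  }
  i <- 2:(n - 1)
  cand <- i[ecg[i] > ecg[i - 1] & ecg[i] >= ecg[i + 1] & ecg[i] > thr]
  if (length(cand) == 0) {
    pwv_abort("fewer than 3 R-peaks found", "insufficient_signal")
  }
  # greedy non-maximum suppression within the refractory period
  cand <- cand[order(ecg[cand], decreasing = TRUE)]
  gap <- round(refractory * sampling_rate)
  keep <- integer(0)
  for (c0 in cand) {
    if (!length(keep) || all(abs(keep - c0) >= gap)) keep <- c(keep, c0)
  }
  keep <- sort(keep)
  if (length(keep) < 3) {
    pwv_abort("fewer than 3 R-peaks found", "insufficient_signal")
  }
  # parabolic refinement of the discrete peak
  y0 <- ecg[keep - 1]
  y1 <- ecg[keep]
  y2 <- ecg[keep + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  (keep - 1 + delta) / sampling_rate
}

window_indices <- function(start, end, sampling_rate, n) {
  i1 <- max(1L, floor(start * sampling_rate) + 1L)
  i2 <- min(n, floor(end * sampling_rate) + 1L)
  if (i2 < i1) integer(0) else i1:i2
}

fit_line <- function(t, x) {
  tm <- mean(t)
  xm <- mean(x)
  b <- sum((t - tm) * (x - xm)) / sum((t - tm)^2)
  c(intercept = xm - b * tm, slope = b)
}

#' Detect the pulse foot on a cuff channel
#'
#' Intersecting-tangents foot definition, the standard convention for
#' transit-time PWV: within each search window the foot is the crossing of
#' (i) the horizontal baseline fitted to the pre-upstroke segment and (ii) the
#' tangent fitted through the region of maximum upstroke slope. For a signal
#' whose leading edge is linear (and for any ramp) the construction is exact.
#' Windows without a detectable upstroke (amplitude below a noise-scaled
#' threshold, or non-positive slope) yield `NA` with `valid = FALSE` rather
#' than an error, so isolated bad beats are excluded, not fatal.
#'
#' An alternative foot definition, the maximum of the second derivative, is
#' available via `method = "second_derivative"` for sensitivity analyses.
#'
#' @param cuff Numeric cuff-pulse samples.
#' @param sampling_rate Samples per second.
#' @param windows Data frame with one row per expected beat and columns
#'   `start`, `end` (seconds).
#' @param slope_frac Fraction of the maximum derivative defining the tangent
#'   fit region (default 0.9).
#' @param min_snr Minimum upstroke amplitude in units of the baseline noise
#'   MAD (default 6).
#' @param method Foot definition; default `"tangents"`.
#' @return Tibble with columns `beat`, `time`, `valid`.
#' @export
detect_pulse_foot <- function(cuff, sampling_rate, windows, slope_frac = 0.9,
                              min_snr = 6,
                              method = c("tangents", "second_derivative")) {
  method <- match.arg(method)
  n <- length(cuff)
  dt <- 1 / sampling_rate
  out <- purrr::map_dfr(seq_len(nrow(windows)), function(b) {
    flag <- tibble::tibble(beat = b, time = NA_real_, valid = FALSE)
    idx <- window_indices(windows$start[b], windows$end[b], sampling_rate, n)
    if (length(idx) < round(0.12 * sampling_rate)) {
      return(flag)
    }
    tt <- (idx - 1) * dt
    xs <- moving_average(cuff[idx], round(0.007 * sampling_rate))
    # slope from a central difference over +/- 4 ms, then smoothed: the
    # single-sample difference is too noisy to anchor the tangent on
    h <- max(1L, round(0.004 * sampling_rate))
    nw <- length(xs)
    d <- numeric(nw)
    if (nw > 2 * h) {
      d[(h + 1):(nw - h)] <- (xs[(2 * h + 1):nw] - xs[1:(nw - 2 * h)]) / (2 * h * dt)
    }
    d <- moving_average(d, round(0.005 * sampling_rate))
    imax <- which.max(d)
    dmax <- d[imax]
    base_idx <- which(tt < tt[imax] - 0.025)
    if (length(base_idx) < 5 || !is.finite(dmax) || dmax <= 0) {
      return(flag)
    }
    base_level <- stats::median(xs[base_idx])
    base_noise <- stats::mad(cuff[idx][base_idx])
    amp <- max(xs) - base_level
    if (amp < max(min_snr * base_noise, 1e-9)) {
      return(flag)
    }
    if (method == "second_derivative") {
      d2 <- c(0, diff(d)) / dt
      pre <- seq_len(imax)
      t_foot <- tt[pre][which.max(d2[pre])]
    } else {
      run <- d >= slope_frac * dmax
      lo <- imax
      while (lo > 1 && run[lo - 1]) lo <- lo - 1
      hi <- imax
      while (hi < length(run) && run[hi + 1]) hi <- hi + 1
      reg <- lo:hi
      if (length(reg) < 2) reg <- max(1, imax - 1):min(length(tt), imax + 1)
      ln <- fit_line(tt[reg], xs[reg])
      if (!is.finite(ln["slope"]) || ln["slope"] <= 0) {
        return(flag)
      }
      t_foot <- (base_level - ln["intercept"]) / ln["slope"]
    }
    if (!is.finite(t_foot) || t_foot < tt[1] - 0.005 || t_foot > tt[imax]) {
      return(flag)
    }
    tibble::tibble(beat = b, time = unname(t_foot), valid = TRUE)
  })
  out
}

#' Detect aortic valve opening on a Doppler envelope
#'
#' Within each search window the onset of the ejection burst is located as the
#' first crossing of `threshold` times the window's peak amplitude (above the
#' local baseline), backward-corrected to the baseline level by linear
#' extrapolation of the local slope at the crossing. With `threshold = 0` the
#' detection degenerates to the first sample above baseline.
#'
#' @param doppler_env Numeric Doppler envelope samples.
#' @inheritParams detect_pulse_foot
#' @param threshold Fraction of the peak envelope amplitude (default 0.10).
#' @return Tibble with columns `beat`, `time`, `valid`.
#' @export
detect_valve_opening <- function(doppler_env, sampling_rate, windows,
                                 threshold = 0.10, min_snr = 6) {
  n <- length(doppler_env)
  dt <- 1 / sampling_rate
  purrr::map_dfr(seq_len(nrow(windows)), function(b) {
    flag <- tibble::tibble(beat = b, time = NA_real_, valid = FALSE)
    idx <- window_indices(windows$start[b], windows$end[b], sampling_rate, n)
    if (length(idx) < round(0.04 * sampling_rate)) {
      return(flag)
    }
    tt <- (idx - 1) * dt
    xs <- moving_average(doppler_env[idx], round(0.005 * sampling_rate))
    nb <- max(5L, round(0.012 * sampling_rate))
    base_level <- stats::median(xs[seq_len(nb)])
    base_noise <- stats::mad(doppler_env[idx][seq_len(nb)])
    amp <- max(xs) - base_level
    if (amp < max(min_snr * base_noise, 1e-9)) {
      return(flag)
    }
    level <- base_level + threshold * amp
    above <- which(xs > level)
    above <- above[above > nb]
    if (!length(above)) {
      return(flag)
    }
    ic <- above[1]
    reg <- max(1, ic - round(0.002 * sampling_rate)):min(length(tt), ic + round(0.006 * sampling_rate))
    ln <- fit_line(tt[reg], xs[reg])
    if (!is.finite(ln["slope"]) || ln["slope"] <= 0) {
      return(flag)
    }
    t_valve <- tt[ic] - (xs[ic] - base_level) / ln["slope"]
    if (!is.finite(t_valve) || t_valve < tt[1] - 0.005 || t_valve > tt[length(tt)]) {
      return(flag)
    }
    tibble::tibble(beat = b, time = unname(t_valve), valid = TRUE)
  })
}

#' Assemble per-beat fiducials from event time vectors
#'
#' Greedy per-beat matching: each R-peak is paired with the first valve
#' opening and the first subsequent pulse foot occurring before the next
#' R-peak. Beats missing either event, or violating the physiological
#' ordering R-peak < valve opening < pulse foot, are flagged invalid and
#' excluded from downstream averaging.
#'
#' @param r_times,valve_times,foot_times Time-sorted numeric vectors, seconds.
#' @return A tibble of class `pwv_fiducials` with columns `beat_index`,
#'   `t_r_hat`, `t_valve_hat`, `t_foot_hat`, `valid`.
#' @export
assemble_fiducials <- function(r_times, valve_times, foot_times) {
  for (v in list(r_times, valve_times, foot_times)) {
    if (is.unsorted(v, strictly = FALSE)) {
      pwv_abort("event time vectors must be sorted in time", "invalid_input")
    }
  }
  nxt <- c(r_times[-1], Inf)
  rows <- purrr::map_dfr(seq_along(r_times), function(i) {
    v <- valve_times[valve_times > r_times[i] & valve_times < nxt[i]]
    v <- if (length(v)) v[1] else NA_real_
    f <- foot_times[foot_times > r_times[i] & foot_times < nxt[i]]
    if (!is.na(v)) f <- f[f > v]
    f <- if (length(f)) f[1] else NA_real_
    tibble::tibble(
      beat_index = i, t_r_hat = r_times[i], t_valve_hat = v, t_foot_hat = f,
      valid = !is.na(v) && !is.na(f) && r_times[i] < v && v < f
    )
  })
  if (!any(rows$valid)) {
    pwv_abort("no valid beats after fiducial matching", "insufficient_signal")
  }
  structure(rows, class = c("pwv_fiducials", class(rows)))
}

#' Detect all fiducials of a waveform bundle
#'
#' Runs [detect_r_peaks()] on the ECG, builds per-beat search windows from the
#' detected R-peaks, locates valve openings ([detect_valve_opening()]) and
#' pulse feet ([detect_pulse_foot()]), and assembles a per-beat
#' [assemble_fiducials()] table. The truth annotations of the bundle are never
#' consulted.
#'
#' @param bundle A `waveform_bundle` from [synthesize_recording()] or
#'   [read_waveform_bundle()].
#' @param k,refractory R-peak detector settings, see [detect_r_peaks()].
#' @param valve_threshold Envelope onset threshold, see [detect_valve_opening()].
#' @param foot_method Foot definition, see [detect_pulse_foot()].
#' @param valve_window,foot_window Search window offsets after each R-peak,
#'   seconds `c(start, end)`.
#' @return A `pwv_fiducials` tibble with attributes `subject_id` and
#'   `sampling_rate`.
#' @examples
#' s <- draw_cohort(pwv_preset("single_subject"), seed = 1)
#' b <- synthesize_recording(s, duration = 10, sampling_rate = 500, seed = 2)
#' detect_fiducials(b)
#' @export
detect_fiducials <- function(bundle, k = 6, refractory = 0.3,
                             valve_threshold = 0.10,
                             foot_method = c("tangents", "second_derivative"),
                             valve_window = c(0.01, 0.18),
                             foot_window = c(0.08, 0.55)) {
  foot_method <- match.arg(foot_method)
  stopifnot(inherits(bundle, "waveform_bundle"))
  fs <- bundle$sampling_rate
  ch <- bundle$channels
  r <- detect_r_peaks(ch$ecg, fs, k = k, refractory = refractory)
  nxt <- c(r[-1], bundle$duration)
  vw <- tibble::tibble(
    start = r + valve_window[1],
    end = pmin(r + valve_window[2], nxt - 0.01)
  )
  fw <- tibble::tibble(
    start = r + foot_window[1],
    end = pmin(r + foot_window[2], nxt - 0.02, bundle$duration)
  )
  valve <- detect_valve_opening(ch$doppler_env, fs, vw, threshold = valve_threshold)
  foot <- detect_pulse_foot(ch$cuff, fs, fw, method = foot_method)
  fid <- assemble_fiducials(
    r,
    sort(valve$time[valve$valid]),
    sort(foot$time[foot$valid])
  )
  attr(fid, "subject_id") <- bundle$subject_id
  attr(fid, "sampling_rate") <- fs
  fid
}
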