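# Shared fixture builders. Everything is generated in code; no stored data.

# A subject with fully controlled hemodynamics, defaulting to round numbers
# that make transit-time arithmetic easy to check by hand.
fixture_subject <- function(heart_rate = 60, ict = 0.06, distance = 1.0,
                            true_pwv = 5.0, age = 40, map = 90,
                            entered_age = 40, subject_id = "fix_001") {
  tibble::tibble(
    subject_id = subject_id, age = age, entered_age = entered_age,
    sex = "male", bmi = 24, sbp = map + 20, dbp = map - 10, map = map,
    heart_rate = heart_rate, true_pwv = true_pwv, ict = ict, distance = distance
  )
}

# Fast clean or noisy recording for detector tests.
fixture_bundle <- function(subject = fixture_subject(), duration = 10,
                           sampling_rate = 1000, noise_sd = 0, seed = 421,
                           jitter_sd = 0) {
  synthesize_recording(
    subject,
    duration = duration, sampling_rate = sampling_rate,
    noise_sd = noise_sd, jitter_sd = jitter_sd, seed = seed
  )
}

# Per-beat absolute detection errors (in seconds) of a bundle's fiducials
# against its own truth annotations, matched by beat order of valid beats.
fiducial_errors <- function(bundle, ...) {
  fid <- detect_fiducials(bundle, ...)
  ok <- fid[fid$valid, ]
  truth <- bundle$truth[ok$beat_index, ]
  tibble::tibble(
    r = abs(ok$t_r_hat - truth$t_r),
    valve = abs(ok$t_valve_hat - truth$t_valve),
    foot = abs(ok$t_foot_hat - truth$t_foot)
  )
}
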