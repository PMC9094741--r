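make_fiducials <- function(pat = 0.26, ict = 0.06, n = 5) {
  r <- seq_len(n)
  assemble_fiducials(r, r + ict, r + pat)
}

test_that("corrected PAT is the mean PAT minus the mean ICT", {
  cp <- corrected_pat(make_fiducials(pat = 0.26, ict = 0.06))
  expect_equal(cp$pat, 0.26, tolerance = 1e-12)
  expect_equal(cp$ict_hat, 0.06, tolerance = 1e-12)
  expect_equal(cp$cpat, 0.20, tolerance = 1e-12)
  expect_equal(cp$n_beats, 5L)
})

test_that("corrected PAT rejects implausible or insufficient input", {
  fid <- make_fiducials(n = 5)
  fid$valid[3:5] <- FALSE
  expect_error(corrected_pat(fid), class = "pwvagree_insufficient_signal")
  # ICT >= PAT cannot happen with valid ordering, so force it
  bad <- make_fiducials(pat = 0.26, ict = 0.06)
  bad$t_valve_hat <- bad$t_r_hat + 0.30
  bad$t_foot_hat <- bad$t_r_hat + 0.26
  bad$valid <- TRUE
  expect_error(corrected_pat(bad), class = "pwvagree_implausible_timing")
})

test_that("measured PWV divides distance by corrected PAT", {
  expect_equal(measured_pwv(1.0, 0.20), 5.0)
  expect_equal(measured_pwv(0.96, 0.20), 4.8)
  expect_error(measured_pwv(1.0, 0), class = "pwvagree_invalid_input")
  expect_error(measured_pwv(-1, 0.2), class = "pwvagree_invalid_input")
})

test_that("the noise-free pipeline reproduces true PWV within 1 percent", {
  cohort <- draw_cohort("agbresa", seed = 42)[1:4, ]
  rec <- compute_pwv(cohort,
    duration = 12, sampling_rate = 500,
    noise_sd = 0, seed = 1
  )
  expect_true(all(abs(rec$measured_pwv / rec$true_pwv - 1) < 0.01))
  # corrected PAT recovered within 5 ms of the subject's true transit time
  true_cpat <- cohort$distance / cohort$true_pwv
  expect_true(all(abs(rec$cpat - true_cpat) < 0.005))
})

test_that("the triplicate protocol has the stated noise decomposition", {
  grid <- tibble::tibble(entered_age = rep(55L, 2e4), map = 90)
  core <- estimate_pwv_core(55, 90)
  # zero noise: all repetitions equal the deterministic core
  silent <- estimate_pwv_protocol(grid[1:5, ], sigma_b = 0, sigma_r = 0, seed = 1)
  expect_equal(silent$est_rep1, rep(core, 5))
  expect_equal(silent$est_rep2, silent$est_rep3)
  expect_equal(silent$estimated_pwv, rep(core, 5))
  # var of the rep-mean across draws ~ sigma_b^2 + sigma_r^2 / 3
  out <- estimate_pwv_protocol(grid, sigma_b = 0.1, sigma_r = 0.1, seed = 2)
  expect_equal(var(out$estimated_pwv - core), 0.01 + 0.01 / 3, tolerance = 0.05)
  # spread of the three reps around their subject mean ~ sigma_r
  reps <- cbind(out$est_rep1, out$est_rep2, out$est_rep3)
  within_sd <- sqrt(mean(apply(reps, 1, var)))
  expect_equal(within_sd, 0.1, tolerance = 0.05)
})

test_that("the entered-age experiment isolates the device's age dependence", {
  # noise-free: the quadratic fits its own generating polynomial exactly
  res0 <- entered_age_experiment(sigma_r = 0, seed = 3)
  expect_equal(res0$r_squared, 1, tolerance = 1e-12)
  cf <- surrogate_coefs()
  expect_equal(unname(res0$coefficients[2]), unname(cf["c1"]), tolerance = 1e-9)
  expect_equal(unname(res0$coefficients[3]), unname(cf["c2"]), tolerance = 1e-9)
  # R-squared does not depend on the (random) order of entry
  res_a <- entered_age_experiment(seed = 11)
  perm <- res_a$measurements[sample(nrow(res_a$measurements)), ]
  refit <- summary(lm(value ~ entered_age + I(entered_age^2), data = perm))
  expect_equal(refit$r.squared, res_a$r_squared, tolerance = 1e-12)
  # a constant subject deviation changes values but not the fit quality
  res_b <- entered_age_experiment(seed = 11, subject_bias = 0.5)
  expect_equal(res_b$r_squared, res_a$r_squared, tolerance = 1e-10)
  # degenerate grids are rejected
  expect_error(
    entered_age_experiment(ages = 50),
    class = "pwvagree_invalid_input"
  )
  expect_error(
    entered_age_experiment(ages = c(40, 50)),
    class = "pwvagree_invalid_input"
  )
})

test_that("per-repetition spread in the entered-age experiment matches sigma_r", {
  sds <- purrr::map_dbl(1:30, function(i) {
    res <- entered_age_experiment(seed = 100 + i)
    m <- res$measurements
    sqrt(mean(tapply(m$value, m$order, var)))
  })
  expect_equal(mean(sds), 0.1, tolerance = 0.15)
})

test_that("pipeline failures carry the subject id", {
  cohort <- draw_cohort("agbresa", seed = 3)[1:3, ]
  cohort$heart_rate[2] <- 25 # too slow for 3 beats in a short recording
  expect_error(
    compute_pwv(cohort, duration = 5, sampling_rate = 500, seed = 1),
    regexp = cohort$subject_id[2],
    class = "pwvagree_stage_error"
  )
})
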