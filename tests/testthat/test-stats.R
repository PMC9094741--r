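sim_outcome_cohort <- function(n = 200, seed = 1, noise = 0.2) {
  withr::with_seed(seed, {
    tibble::tibble(
      age = runif(n, 20, 80),
      map = rnorm(n, 90, 8),
      sex = sample(c("male", "female"), n, replace = TRUE),
      bmi = rnorm(n, 24, 3)
    ) |>
      dplyr::mutate(y = 2 + 0.05 * age + 0.001 * age^2 + rnorm(n, 0, noise))
  })
}

test_that("a deterministic quadratic outcome is fit perfectly", {
  d <- sim_outcome_cohort(noise = 0)
  m <- suppressWarnings(quadratic_model(d, "y", covariates = NULL))
  expect_equal(m$r_squared, 1, tolerance = 1e-9)
  expect_equal(m$standardized$beta[m$standardized$term == "age_poly"], 1,
    tolerance = 1e-6
  )
  expect_equal(r_squared_age_alone(d, "y"), 1, tolerance = 1e-9)
})

test_that("pure noise explains nothing", {
  d <- sim_outcome_cohort(n = 1e4, seed = 2)
  d$y <- withr::with_seed(3, rnorm(nrow(d)))
  m <- quadratic_model(d, "y")
  expect_lt(m$r_squared, 0.01)
})

test_that("degenerate designs raise a singular-design error", {
  d <- sim_outcome_cohort(n = 50, seed = 4)
  d$age <- 50
  expect_error(quadratic_model(d, "y", covariates = NULL),
    class = "pwvagree_singular_design"
  )
  d2 <- sim_outcome_cohort(n = 50, seed = 5)
  d2$bmi <- d2$map # collinear covariates
  expect_error(quadratic_model(d2, "y"), class = "pwvagree_singular_design")
})

test_that("regression input validation", {
  d <- sim_outcome_cohort(n = 8)
  expect_error(quadratic_model(d, "y"), class = "pwvagree_invalid_input")
  d2 <- sim_outcome_cohort(n = 30)
  d2$y[4] <- NA
  expect_error(quadratic_model(d2, "y"), class = "pwvagree_invalid_input")
  expect_error(
    quadratic_model(sim_outcome_cohort(30), "absent"),
    class = "pwvagree_invalid_input"
  )
})

test_that("R-squared never decreases when predictors are added", {
  for (seed in 1:5) {
    co <- draw_cohort("athletes", seed = seed) |>
      estimate_pwv_protocol(seed = seed + 50)
    r2_age <- r_squared_age_alone(co, "estimated_pwv")
    r2_map <- quadratic_model(co, "estimated_pwv", covariates = "map")$r_squared
    r2_full <- quadratic_model(co, "estimated_pwv")$r_squared
    expect_gte(r2_map, r2_age - 1e-12)
    expect_gte(r2_full, r2_map - 1e-12)
  }
})

test_that("standardized betas reproduce the printed cohort values", {
  # athletes: age beta 0.93 and MAP beta 0.14 at printed precision (+/- 0.02)
  betas <- purrr::map_dfr(1:30, function(i) {
    co <- draw_cohort("athletes", seed = 7000 + i) |>
      estimate_pwv_protocol(seed = 7500 + i)
    m <- quadratic_model(co, "estimated_pwv")
    b <- m$standardized
    tibble::tibble(
      age = b$beta[b$term == "age_poly"],
      map = b$beta[b$term == "map"],
      sex = b$beta[b$term == "sex"],
      bmi = b$beta[b$term == "bmi"]
    )
  })
  expect_lt(abs(mean(betas$age) - 0.93), 0.02)
  expect_lt(abs(mean(betas$map) - 0.14), 0.04)
  # sex and BMI play no role, by construction and by fit
  expect_lt(abs(mean(betas$sex)), 0.02)
  expect_lt(abs(mean(betas$bmi)), 0.02)
})

test_that("Bland-Altman summarizes paired differences", {
  d <- tibble::tibble(est = c(5, 6, 7), meas = c(4, 5, 6), age = c(30, 40, 50))
  ba <- bland_altman(d, "est", "meas", "age")
  expect_equal(ba$mean_difference, 1.0)
  expect_equal(ba$sd_difference, 0)
  expect_equal(unname(ba$limits_of_agreement), c(1, 1))
  ident <- tibble::tibble(est = c(4.2, 5.1, 6.3, 7), meas = c(4.2, 5.1, 6.3, 7),
    age = c(30, 40, 50, 60))
  ba2 <- bland_altman(ident, "est", "meas", "age")
  expect_equal(ba2$mean_difference, 0)
  expect_equal(ba2$sd_difference, 0)
  expect_equal(ba2$diff_vs_age_slope, 0)
  expect_error(
    bland_altman(d[, c("est", "age")], "est", "meas", "age"),
    class = "pwvagree_invalid_input"
  )
  expect_error(bland_altman(d[1:2, ], "est", "meas", "age"),
    class = "pwvagree_invalid_input"
  )
})

test_that("the Bland-Altman mean difference is exactly the difference of means", {
  withr::with_seed(8, {
    d <- tibble::tibble(
      est = rnorm(50, 6, 1), meas = rnorm(50, 5, 0.6), age = runif(50, 20, 80)
    )
  })
  ba <- bland_altman(d, "est", "meas", "age")
  expect_equal(ba$mean_difference, mean(d$est) - mean(d$meas), tolerance = 1e-12)
  expect_equal(
    unname(ba$limits_of_agreement),
    ba$mean_difference + c(-1.96, 1.96) * ba$sd_difference
  )
})

test_that("partial correlation given age behaves at its edge cases", {
  withr::with_seed(9, {
    age <- runif(200, 20, 80)
    x <- 1 + 0.05 * age + rnorm(200, 0, 0.3)
  })
  self <- partial_correlation_given_age(x, x, age)
  expect_equal(self$r, 1, tolerance = 1e-9)
  # y an exact function of age: residuals of y vanish
  y_det <- 2 + 0.03 * age + 1e-4 * age^2
  expect_error(
    partial_correlation_given_age(x, y_det, age),
    class = "pwvagree_undefined_correlation"
  )
  # y almost a pure function of age: nothing left to correlate with x
  y_near <- y_det + withr::with_seed(10, rnorm(200, 0, 0.01))
  near <- partial_correlation_given_age(x, y_near, age)
  expect_lt(abs(near$r), 0.3)
  expect_error(partial_correlation_given_age(x[1:4], x[1:4], age[1:4]),
    class = "pwvagree_invalid_input"
  )
  expect_error(partial_correlation_given_age(x, x[1:10], age),
    class = "pwvagree_invalid_input"
  )
})

test_that("variables independent given age have near-zero partial correlation", {
  rs <- purrr::map_dbl(1:200, function(i) {
    withr::with_seed(2000 + i, {
      age <- rnorm(24, 33, 9)
      x <- 0.1 * age + rnorm(24)
      y <- 0.05 * age + rnorm(24)
    })
    partial_correlation_given_age(x, y, age)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("normality testing is calibrated", {
  flags <- purrr::map_lgl(1:20, function(i) {
    ks_normality(withr::with_seed(300 + i, rnorm(5000)))$normal
  })
  expect_gte(mean(flags), 0.9)
  expo <- ks_normality(withr::with_seed(11, rexp(5000)))
  expect_false(expo$normal)
  expect_true(expo$statistic >= 0 && expo$statistic <= 1)
  plain <- ks_normality(withr::with_seed(12, rnorm(1000)), lilliefors = FALSE)
  expect_true(plain$statistic >= 0 && plain$statistic <= 1)
  expect_error(ks_normality(rep(1, 100)), class = "pwvagree_degenerate_input")
  expect_error(ks_normality(c(1, 2, 3)), class = "pwvagree_invalid_input")
})

test_that("the closed-form oracle matches Monte Carlo at scale", {
  for (nm in c("agbresa", "athletes")) {
    preset <- pwv_preset(nm, n = 1e5)
    oracle <- variance_decomposition_oracle(preset)
    big <- draw_cohort(preset, seed = 77) |>
      estimate_pwv_protocol(seed = 78)
    meas <- big$true_pwv # model-level measured PWV
    fit_est <- summary(lm(estimated_pwv ~ age + I(age^2), data = big))
    fit_meas <- summary(lm(meas ~ age + I(age^2), data = big))
    expect_equal(mean(big$estimated_pwv), oracle$e_estimated, tolerance = 0.05)
    expect_equal(mean(meas), oracle$e_measured, tolerance = 0.05)
    expect_equal(mean(big$estimated_pwv - meas), oracle$e_difference, tolerance = 0.05)
    expect_equal(fit_est$r.squared, oracle$r2_est_age, tolerance = 0.02)
    expect_equal(fit_meas$r.squared, oracle$r2_meas_age, tolerance = 0.02)
    expect_equal(cor(big$estimated_pwv, meas)^2, oracle$r2_est_meas, tolerance = 0.02)
  }
})

test_that("the oracle rejects degenerate presets", {
  degenerate <- pwv_preset("single_subject")
  expect_error(
    variance_decomposition_oracle(degenerate),
    class = "pwvagree_unsupported_model"
  )
})

test_that("truncated normal moments are exact", {
  # untruncated: the classic normal moments
  m <- truncnorm_moments(2, 3)
  expect_equal(m$mean, 2)
  expect_equal(m$var, 9)
  expect_equal(m$m3, 2^3 + 3 * 2 * 9)
  expect_equal(m$m4, 2^4 + 6 * 2^2 * 9 + 3 * 81)
  # truncated: against a large Monte Carlo sample
  mt <- truncnorm_moments(33, 9, 18, 70)
  draws <- withr::with_seed(13, {
    x <- rnorm(4e5, 33, 9)
    x[x >= 18 & x <= 70]
  })
  expect_equal(mt$mean, mean(draws), tolerance = 0.01)
  expect_equal(mt$var, var(draws), tolerance = 0.01)
  expect_equal(mt$m3, mean(draws^3), tolerance = 0.01)
  expect_equal(mt$m4, mean(draws^4), tolerance = 0.01)
})

test_that("tidiers return well-formed tibbles", {
  co <- draw_cohort("athletes", seed = 21) |> estimate_pwv_protocol(seed = 22)
  m <- quadratic_model(co, "estimated_pwv")
  td <- generics::tidy(m)
  expect_true(all(c("term", "estimate", "std_beta", "p_value") %in% names(td)))
  expect_equal(nrow(td), 6) # intercept, age, age^2, map, sex, bmi
  gl <- generics::glance(m)
  expect_equal(gl$r.squared, m$r_squared)
  withr::with_seed(23, {
    d <- tibble::tibble(
      est = rnorm(30, 6), meas = rnorm(30, 5), age = runif(30, 20, 80)
    )
  })
  ba <- bland_altman(d, "est", "meas", "age")
  expect_equal(nrow(generics::tidy(ba)), 8)
  expect_equal(generics::glance(ba)$nobs, 30)
  ea <- entered_age_experiment(seed = 24)
  expect_equal(generics::glance(ea)$r.squared, ea$r_squared)
  expect_equal(nrow(generics::tidy(ea)), 18)
})
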