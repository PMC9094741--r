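test_that("map_from_cuff follows the one-third pulse pressure convention", {
  expect_equal(map_from_cuff(125, 70), 70 + 55 / 3, tolerance = 1e-12)
  expect_equal(round(map_from_cuff(125, 70), 2), 88.33)
  expect_equal(round(map_from_cuff(128, 78), 2), 94.67)
  # vectorized and always strictly inside (dbp, sbp)
  sbp <- c(110, 135, 160)
  dbp <- c(60, 85, 95)
  m <- map_from_cuff(sbp, dbp)
  expect_true(all(m > dbp & m < sbp))
  expect_error(map_from_cuff(90, 90), class = "pwvagree_invalid_input")
  expect_error(map_from_cuff(120, -5), class = "pwvagree_invalid_input")
  expect_error(map_from_cuff(80, 120), class = "pwvagree_invalid_input")
})

test_that("the surrogate core is monotone with a fixed linear MAP effect", {
  cf <- surrogate_coefs()
  # vertex of the age quadratic lies below the valid age domain
  expect_lt(-cf["c1"] / (2 * cf["c2"]), 18)
  ages <- seq(18, 100, by = 0.5)
  f <- estimate_pwv_core(ages, 90)
  expect_true(all(diff(f) > 0))
  for (a in c(18, 33, 56, 80)) {
    for (m in c(60, 88.3, 120)) {
      expect_equal(
        estimate_pwv_core(a, m + 1) - estimate_pwv_core(a, m),
        unname(cf["c3"]),
        tolerance = 1e-12
      )
    }
  }
  maps <- seq(50, 140, by = 1)
  expect_true(all(diff(estimate_pwv_core(50, maps)) > 0))
  expect_error(estimate_pwv_core(10, 90), class = "pwvagree_invalid_input")
  expect_error(estimate_pwv_core(50, 145), class = "pwvagree_invalid_input")
})

test_that("surrogate cohort expectations reproduce the calibration anchors", {
  # the oracle folds in the Jensen term c2 * var(age) and the MAP anchoring
  agb <- variance_decomposition_oracle(pwv_preset("agbresa"))
  ath <- variance_decomposition_oracle(pwv_preset("athletes"))
  expect_equal(agb$e_estimated, 5.8, tolerance = 0.015)
  expect_equal(ath$e_estimated, 8.3, tolerance = 0.015)
})

test_that("true aortic PWV is linear in age with the calibrated mean", {
  expect_equal(true_pwv_model(33, noise = FALSE), 4.80, tolerance = 1e-12)
  ages <- seq(20, 80, by = 5)
  v <- true_pwv_model(ages, noise = FALSE)
  expect_equal(unique(round(diff(v) / 5, 12)), 0.04)
  expect_error(true_pwv_model(-3), class = "pwvagree_invalid_input")
})

test_that("R-squared of true PWV on age matches the variance decomposition", {
  # closed form: (0.04 * 9)^2 / ((0.04 * 9)^2 + 0.33^2) = 0.543 for
  # untruncated Normal(33, 9) ages
  closed_form <- (0.04 * 9)^2 / ((0.04 * 9)^2 + 0.33^2)
  withr::with_seed(101, {
    age <- rnorm(1e5, 33, 9)
    age <- age[age > 0] # the model is defined for non-negative ages
    v <- true_pwv_model(age)
    expect_equal(cor(v, age)^2, closed_form, tolerance = 0.02)
  })
})

test_that("draw_cohort is reproducible and honours the preset", {
  c1 <- draw_cohort("agbresa", seed = 7)
  c2 <- draw_cohort("agbresa", seed = 7)
  expect_equal(tibble::as_tibble(c1), tibble::as_tibble(c2))
  c3 <- draw_cohort("agbresa", seed = 8)
  expect_false(isTRUE(all.equal(c1$age, c3$age)))

  ath <- draw_cohort("athletes", seed = 1)
  expect_equal(nrow(ath), 129)
  expect_true(abs(mean(ath$age) - 56) < 3)
  expect_true(all(ath$age >= 35 & ath$age <= 86))

  agb <- draw_cohort("agbresa", seed = 2)
  preset <- attr(agb, "preset")
  expect_equal(nrow(agb), 24)
  expect_true(all(agb$age >= preset$age_range[1] & agb$age <= preset$age_range[2]))
  # subject-level physiological invariants
  expect_true(all(agb$sbp > agb$dbp & agb$dbp > 0))
  expect_true(all(agb$dbp < agb$map & agb$map < agb$sbp))
  expect_true(all(agb$ict >= 0.03 & agb$ict <= 0.12))
  expect_true(all(agb$distance >= 0.8 & agb$distance <= 1.2))
  expect_true(all(agb$true_pwv > 0))
  expect_false(anyDuplicated(agb$subject_id) > 0)
  expect_equal(agb$entered_age, as.integer(round(agb$age)))
})

test_that("cohort moments recover the generator's designed means", {
  n_rep <- 100
  preset <- pwv_preset("agbresa")
  pooled <- purrr::map_dfr(seq_len(n_rep), function(i) {
    draw_cohort(preset, seed = 10000 + i)[, c("age", "sbp", "dbp", "bmi")]
  })
  n_tot <- nrow(pooled)
  # age: against the truncated-normal expectation (the clip shifts the mean)
  age_expect <- truncnorm_moments(
    preset$age_mean, preset$age_sd,
    preset$age_range[1], preset$age_range[2]
  )$mean
  expect_true(abs(mean(pooled$age) - age_expect) < 3 * sd(pooled$age) / sqrt(n_tot))
  # blood pressures and BMI: against preset means (MAP anchoring makes the
  # cuff-pressure means exact in expectation)
  for (v in c("sbp", "dbp", "bmi")) {
    se <- sd(pooled[[v]]) / sqrt(n_tot)
    expect_true(
      abs(mean(pooled[[v]]) - preset[[paste0(v, "_mean")]]) < 3 * se,
      label = paste0("mean of ", v, " within 3 SE")
    )
  }
})

test_that("presets validate their configuration", {
  expect_error(pwv_preset("agbresa", n = 0), class = "pwvagree_config_error")
  expect_error(pwv_preset("agbresa", age_sd = -1), class = "pwvagree_config_error")
  expect_error(
    pwv_preset("athletes", age_range = c(90, 30)),
    class = "pwvagree_config_error"
  )
  expect_error(pwv_preset("agbresa", nonsense = 1), class = "pwvagree_config_error")
})

test_that("presets round-trip through YAML and packaged defaults load", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "agbresa", n = 12, age_mean = 40), path)
  p <- read_preset(path)
  expect_s3_class(p, "pwv_preset")
  expect_equal(p$n, 12L)
  expect_equal(p$age_mean, 40)
  expect_equal(p$sbp_mean, pwv_preset("agbresa")$sbp_mean)

  shipped <- system.file("extdata", "presets.yaml", package = "pwvagree")
  for (nm in c("athletes", "agbresa", "single_subject")) {
    ps <- read_preset(shipped, which = nm)
    expect_equal(ps$n, pwv_preset(nm)$n)
    expect_equal(ps$age_mean, pwv_preset(nm)$age_mean)
  }
  expect_error(read_preset(shipped, which = "nope"), class = "pwvagree_config_error")
})
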