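#' Quadratic regression with standardized coefficients
#'
#' Ordinary least squares of an outcome on age, age squared, and an optional
#' covariate subset (`map`, `sex`, `bmi`), the model form used throughout the
#' analysis of estimated PWV. Standardized betas are computed on z-scored
#' outcome and predictors, with the fitted age polynomial
#' \eqn{\hat c_1 \cdot age + \hat c_2 \cdot age^2} treated as a single
#' composite predictor so that "age" receives one beta, comparable in
#' magnitude to the covariate betas. `sex` is coded male = 1 before scaling.
#'
#' @param data Data frame with an `age` column, the outcome column, and any
#'   requested covariates; at least 10 complete rows.
#' @param outcome Name of the outcome column (string), e.g. `"estimated_pwv"`.
#' @param covariates Character subset of `c("map", "sex", "bmi")`; `NULL` for
#'   the age-only model.
#' @return An object of class `pwv_regression`: list with the raw `fit` (lm),
#'   `coefficients`, `standardized` (tibble `term, beta, p_value`),
#'   `r_squared`, `n`, `outcome`, `predictors`. Supports [generics::tidy()],
#'   [generics::glance()].
#' @examples
#' cohort <- draw_cohort("athletes", seed = 1) |> estimate_pwv_protocol(seed = 2)
#' quadratic_model(cohort, "estimated_pwv")
#' @export
quadratic_model <- function(data, outcome, covariates = c("map", "sex", "bmi")) {
  stopifnot(is.data.frame(data), is.character(outcome), length(outcome) == 1)
  covariates <- if (is.null(covariates)) character(0) else {
    match.arg(covariates, c("map", "sex", "bmi"), several.ok = TRUE)
  }
  need <- c(outcome, "age", covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    pwv_abort(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      "invalid_input"
    )
  }
  df <- data.frame(
    y = data[[outcome]],
    age = data$age
  )
  for (cv in covariates) {
    df[[cv]] <- if (cv == "sex") as.numeric(data$sex == "male") else data[[cv]]
  }
  if (anyNA(df)) pwv_abort("missing values are not allowed", "invalid_input")
  n <- nrow(df)
  if (n < 10) pwv_abort("need at least 10 observations", "invalid_input")
  rhs <- paste(c("age", "I(age^2)", covariates), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("y ~", rhs)), data = df)
  p <- length(stats::coef(fit))
  if (fit$rank < p || any(is.na(stats::coef(fit)))) {
    pwv_abort("design matrix is rank deficient", "singular_design")
  }
  # composite age predictor: the fitted quadratic age polynomial
  cf <- stats::coef(fit)
  age_comp <- cf[["age"]] * df$age + cf[["I(age^2)"]] * df$age^2
  zdf <- data.frame(y = zscore(df$y), age_poly = zscore(age_comp))
  for (cv in covariates) zdf[[cv]] <- zscore(df[[cv]])
  zfit <- stats::lm(y ~ . - 1, data = zdf)
  zsum <- summary(zfit)$coefficients
  standardized <- tibble::tibble(
    term = rownames(zsum),
    beta = zsum[, "Estimate"],
    p_value = zsum[, "Pr(>|t|)"]
  )
  structure(
    list(
      fit = fit,
      coefficients = cf,
      standardized = standardized,
      r_squared = summary(fit)$r.squared,
      n = n,
      outcome = outcome,
      predictors = c("age", "age^2", covariates)
    ),
    class = "pwv_regression"
  )
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    pwv_abort("cannot standardize a constant predictor", "singular_design")
  }
  (x - mean(x)) / s
}

#' @export
print.pwv_regression <- function(x, ...) {
  cat(sprintf(
    "<pwv_regression> %s ~ %s  (n = %d)\n  R^2 = %.4f\n",
    x$outcome, paste(x$predictors, collapse = " + "), x$n, x$r_squared
  ))
  b <- x$standardized
  cat(sprintf(
    "  standardized beta [%s]: %s\n", paste(b$term, collapse = ", "),
    paste(sprintf("%.3f", b$beta), collapse = ", ")
  ))
  invisible(x)
}

#' Variance in an outcome explained by age alone
#'
#' R-squared of the quadratic-in-age-only model, the "age alone" comparison
#' used to show how much of the estimated-PWV variance entered age accounts
#' for.
#'
#' @inheritParams quadratic_model
#' @return A single number in `[0, 1]`.
#' @export
r_squared_age_alone <- function(data, outcome) {
  quadratic_model(data, outcome, covariates = NULL)$r_squared
}

#' Bland-Altman agreement between estimated and measured PWV
#'
#' Mean and SD of the paired differences (estimated minus measured), limits of
#' agreement at mean +/- 1.96 SD, a linear regression of the difference on age
#' (the age-trend of the bias), and the age-adjusted partial correlation
#' between the two methods.
#'
#' @param data Data frame containing the paired values and ages.
#' @param estimated,measured,age Column names (strings).
#' @return An object of class `pwv_agreement`: list with `mean_difference`,
#'   `sd_difference`, `limits_of_agreement`, `diff_vs_age_slope`,
#'   `diff_vs_age_r_squared`, `diff_vs_age_p`, `partial_r_given_age`,
#'   `partial_p`, `n`, and the per-subject `data` used. Supports
#'   [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' rec <- tibble::tibble(est = c(5, 6, 7), meas = c(4, 5, 6), age = c(30, 40, 50))
#' bland_altman(rec, "est", "meas", "age")
#' @export
bland_altman <- function(data, estimated = "estimated_pwv",
                         measured = "measured_pwv", age = "age") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(estimated, measured, age), names(data))
  if (length(missing_cols)) {
    pwv_abort(
      paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
      "invalid_input"
    )
  }
  est <- data[[estimated]]
  meas <- data[[measured]]
  a <- data[[age]]
  if (anyNA(est) || anyNA(meas) || anyNA(a)) {
    pwv_abort("missing values are not allowed", "invalid_input")
  }
  n <- length(est)
  if (n < 3) pwv_abort("need at least 3 paired observations", "invalid_input")
  d <- est - meas
  md <- mean(d)
  sdd <- stats::sd(d)
  fit <- stats::lm(d ~ a)
  fsum <- summary(fit)
  slope_p <- if (stats::sd(a) > 0) fsum$coefficients["a", "Pr(>|t|)"] else NA_real_
  partial <- if (n >= 5 && stats::sd(a) > 0) {
    tryCatch(
      partial_correlation_given_age(est, meas, a),
      pwvagree_error = function(e) tibble::tibble(r = NA_real_, p = NA_real_, n = n)
    )
  } else {
    tibble::tibble(r = NA_real_, p = NA_real_, n = n)
  }
  structure(
    list(
      mean_difference = md,
      sd_difference = sdd,
      limits_of_agreement = c(lower = md - 1.96 * sdd, upper = md + 1.96 * sdd),
      diff_vs_age_slope = unname(stats::coef(fit)[2]),
      diff_vs_age_r_squared = fsum$r.squared,
      diff_vs_age_p = slope_p,
      partial_r_given_age = partial$r,
      partial_p = partial$p,
      n = n,
      data = tibble::tibble(
        estimated = est, measured = meas, age = a,
        difference = d, pair_mean = (est + meas) / 2
      )
    ),
    class = "pwv_agreement"
  )
}

#' @export
print.pwv_agreement <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<pwv_agreement> n = %d\n",
      "  mean difference   %.3f +/- %.3f m/s (LoA %.3f to %.3f)\n",
      "  difference ~ age  slope %.4f m/s per yr, R^2 = %.3f\n",
      "  partial r | age   %.3f (p = %.3f)\n"
    ),
    x$n, x$mean_difference, x$sd_difference,
    x$limits_of_agreement[1], x$limits_of_agreement[2],
    x$diff_vs_age_slope, x$diff_vs_age_r_squared,
    x$partial_r_given_age, x$partial_p
  ))
  invisible(x)
}

#' Partial correlation of two variables given age
#'
#' Residualizes both variables on `{age, age^2}` by least squares and reports
#' the Pearson correlation of the residuals, with a t-based p-value on
#' `n - 4` degrees of freedom. Used to ask whether estimated PWV carries any
#' information about measured PWV beyond what age already provides.
#'
#' @param x,y Numeric vectors of equal length (at least 5).
#' @param age Numeric vector of ages, same length.
#' @return A one-row tibble with `r`, `p`, `n`.
#' @export
partial_correlation_given_age <- function(x, y, age) {
  n <- length(x)
  if (length(y) != n || length(age) != n) {
    pwv_abort("x, y and age must have equal length", "invalid_input")
  }
  if (n < 5) pwv_abort("need at least 5 observations", "invalid_input")
  rx <- stats::resid(stats::lm(x ~ age + I(age^2)))
  ry <- stats::resid(stats::lm(y ~ age + I(age^2)))
  # residuals that are zero up to floating point (a variable that is an exact
  # function of age, or constant) leave the correlation undefined
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), .Machine$double.xmin) ||
    stats::sd(ry) <= 1e-10 * max(stats::sd(y), .Machine$double.xmin)) {
    pwv_abort("residuals are constant; correlation undefined", "undefined_correlation")
  }
  r <- stats::cor(rx, ry)
  df <- n - 4
  tstat <- r * sqrt(df / max(1 - r^2, 1e-15))
  tibble::tibble(r = r, p = 2 * stats::pt(-abs(tstat), df), n = n)
}

#' Normality check with the Kolmogorov-Smirnov statistic
#'
#' Tests a sample against a normal distribution with mean and SD estimated
#' from the sample. Because the parameters are estimated, the Lilliefors
#' correction is applied by default ([nortest::lillie.test()]); the plain
#' one-sample KS test (which is conservative in this situation) is available
#' with `lilliefors = FALSE`.
#'
#' @param values Numeric sample, at least 5 values.
#' @param lilliefors Use the Lilliefors-corrected p-value (default `TRUE`).
#' @param alpha Flag threshold (default 0.05).
#' @return One-row tibble with `statistic`, `p_value`, `normal` (logical),
#'   `method`.
#' @export
ks_normality <- function(values, lilliefors = TRUE, alpha = 0.05) {
  values <- as.numeric(values)
  if (length(values) < 5 || anyNA(values)) {
    pwv_abort("need at least 5 non-missing values", "invalid_input")
  }
  if (stats::sd(values) == 0) {
    pwv_abort("sample is constant; normality test undefined", "degenerate_input")
  }
  if (lilliefors) {
    ht <- nortest::lillie.test(values)
    method <- "lilliefors"
  } else {
    ht <- suppressWarnings(
      stats::ks.test(values, "pnorm", mean(values), stats::sd(values))
    )
    method <- "ks"
  }
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    normal = ht$p.value > alpha,
    method = method
  )
}
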