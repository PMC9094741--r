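# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quadratic PWV regression
#'
#' One row per model term with the raw coefficient and, for the composite age
#' polynomial and each covariate, the standardized beta and its p-value.
#'
#' @param x A `pwv_regression`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_beta`, `p_value`.
#' @method tidy pwv_regression
#' @export
tidy.pwv_regression <- function(x, ...) {
  raw <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
  std <- x$standardized
  std$term[std$term == "age_poly"] <- "age (composite)"
  raw$std_beta <- NA_real_
  raw$p_value <- NA_real_
  for (i in seq_len(nrow(std))) {
    j <- if (std$term[i] == "age (composite)") which(raw$term == "age") else which(raw$term == std$term[i])
    if (length(j) == 1) {
      raw$std_beta[j] <- std$beta[i]
      raw$p_value[j] <- std$p_value[i]
    }
  }
  raw
}

#' @rdname tidy.pwv_regression
#' @method glance pwv_regression
#' @export
glance.pwv_regression <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = summary(x$fit)$adj.r.squared,
    sigma = summary(x$fit)$sigma,
    nobs = x$n
  )
}

#' Tidy a Bland-Altman agreement analysis
#'
#' @param x A `pwv_agreement`.
#' @param ... Unused.
#' @return `tidy()`: one row per agreement quantity (mean difference, SD,
#'   limits, age slope, partial correlation); `glance()`: a one-row summary.
#' @method tidy pwv_agreement
#' @export
tidy.pwv_agreement <- function(x, ...) {
  tibble::tribble(
    ~quantity, ~value,
    "mean_difference", x$mean_difference,
    "sd_difference", x$sd_difference,
    "loa_lower", unname(x$limits_of_agreement[1]),
    "loa_upper", unname(x$limits_of_agreement[2]),
    "diff_vs_age_slope", x$diff_vs_age_slope,
    "diff_vs_age_r_squared", x$diff_vs_age_r_squared,
    "partial_r_given_age", x$partial_r_given_age,
    "partial_p", x$partial_p
  )
}

#' @rdname tidy.pwv_agreement
#' @method glance pwv_agreement
#' @export
glance.pwv_agreement <- function(x, ...) {
  tibble::tibble(
    mean_difference = x$mean_difference,
    sd_difference = x$sd_difference,
    loa_lower = unname(x$limits_of_agreement[1]),
    loa_upper = unname(x$limits_of_agreement[2]),
    diff_vs_age_slope = x$diff_vs_age_slope,
    diff_vs_age_r_squared = x$diff_vs_age_r_squared,
    partial_r_given_age = x$partial_r_given_age,
    partial_p = x$partial_p,
    nobs = x$n
  )
}

#' Tidy an entered-age experiment
#'
#' @param x An `entered_age_result`.
#' @param ... Unused.
#' @return `tidy()`: the measurement grid; `glance()`: quadratic coefficients
#'   and R-squared.
#' @method tidy entered_age_result
#' @export
tidy.entered_age_result <- function(x, ...) {
  x$measurements
}

#' @rdname tidy.entered_age_result
#' @method glance entered_age_result
#' @export
glance.entered_age_result <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    intercept = unname(cf[1]),
    age_linear = unname(cf[2]),
    age_quadratic = unname(cf[3]),
    r.squared = x$r_squared,
    nobs = nrow(x$measurements)
  )
}
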