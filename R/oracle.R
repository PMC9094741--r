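#' Moments of a truncated normal distribution
#'
#' Exact raw moments up to order 4 of `X ~ N(mu, sd^2)` truncated to
#' `[lower, upper]`, via the standard recursion for truncated standard-normal
#' moments
#' \eqn{M_k = (k-1) M_{k-2} - (\beta^{k-1}\phi(\beta) - \alpha^{k-1}\phi(\alpha))/Z}.
#' Used by the variance-decomposition oracle, where plain-normal moment
#' identities would be inaccurate once a preset's age clip truncates the
#' distribution noticeably.
#'
#' @param mu,sd Location and scale of the parent normal.
#' @param lower,upper Truncation bounds (may be infinite).
#' @return List with `mean`, `var`, and raw moments `m1..m4`.
#' @export
truncnorm_moments <- function(mu, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) pwv_abort("sd must be >= 0", "invalid_input")
  if (sd == 0) {
    m <- min(max(mu, lower), upper)
    return(list(mean = m, var = 0, m1 = m, m2 = m^2, m3 = m^3, m4 = m^4))
  }
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z <= 0) pwv_abort("empty truncation interval", "invalid_input")
  pa <- if (is.finite(a)) stats::dnorm(a) else 0
  pb <- if (is.finite(b)) stats::dnorm(b) else 0
  m_std <- numeric(5) # M_0 .. M_4 of the truncated standard normal
  m_std[1] <- 1
  m_std[2] <- (pa - pb) / z
  for (k in 2:4) {
    ta <- if (is.finite(a)) a^(k - 1) * pa else 0
    tb <- if (is.finite(b)) b^(k - 1) * pb else 0
    m_std[k + 1] <- (k - 1) * m_std[k - 1] - (tb - ta) / z
  }
  raw <- vapply(1:4, function(k) {
    j <- 0:k
    sum(choose(k, j) * mu^(k - j) * sd^j * m_std[j + 1])
  }, numeric(1))
  list(
    mean = raw[1], var = raw[2] - raw[1]^2,
    m1 = raw[1], m2 = raw[2], m3 = raw[3], m4 = raw[4]
  )
}

#' Closed-form expectations for a calibrated preset
#'
#' Analytic counterpart of the full simulation, used as the independent
#' oracle in testing: expectations and R-squared values implied by the
#' generator's model equations, computed from exact truncated-normal age
#' moments rather than by Monte Carlo.
#'
#' With age moments \eqn{m_k = E[a^k]} under the preset's truncated normal,
#' the estimated PWV seen through the device surrogate is
#' \eqn{q(a) + c_3 \eta + b + \bar e}, where
#' \eqn{q(a) = (c_1 + 0.35 c_3) a + c_2 a^2} collects the age dependence
#' (direct plus the MAP age trend), \eqn{\eta} is the MAP residual and
#' \eqn{b, \bar e} the protocol noise; measured PWV is linear in age. All
#' variances, covariances and hence the population R-squared values follow in
#' closed form.
#'
#' @param preset A [pwv_preset()].
#' @return A one-row tibble of class `pwv_oracle`: `e_estimated`,
#'   `e_measured`, `e_difference`, `r2_est_age`, `r2_meas_age`, `r2_est_meas`.
#' @examples
#' variance_decomposition_oracle(pwv_preset("agbresa"))
#' @export
variance_decomposition_oracle <- function(preset) {
  if (is.character(preset)) preset <- pwv_preset(preset)
  preset <- validate_preset(preset)
  if (preset$age_sd <= 0 || preset$pwv_sd <= 0) {
    pwv_abort(
      "oracle undefined for a degenerate preset (zero age or PWV variance)",
      "unsupported_model"
    )
  }
  cf <- as.numeric(preset$est_coefs)
  if (length(cf) != 4) {
    pwv_abort("oracle requires the 4-coefficient quadratic surrogate", "unsupported_model")
  }
  m <- truncnorm_moments(
    preset$age_mean, preset$age_sd,
    preset$age_range[1], preset$age_range[2]
  )
  v_age <- m$var
  cov_a_a2 <- m$m3 - m$m1 * m$m2
  v_a2 <- m$m4 - m$m2^2
  map_mean <- preset_map_mean(preset)

  b1 <- cf[2] + preset$map_slope * cf[4] # linear age weight incl. MAP trend
  e_est <- cf[1] + cf[2] * m$m1 + cf[3] * m$m2 + cf[4] * (map_mean - 90)
  v_q <- b1^2 * v_age + cf[3]^2 * v_a2 + 2 * b1 * cf[3] * cov_a_a2
  v_noise <- cf[4]^2 * preset$map_sd^2 + preset$sigma_b^2 + preset$sigma_r^2 / 3
  v_est <- v_q + v_noise

  e_meas <- preset$pwv_intercept + preset$pwv_slope * m$m1
  v_meas <- preset$pwv_slope^2 * v_age + preset$pwv_sd^2
  cov_em <- preset$pwv_slope * (b1 * v_age + cf[3] * cov_a_a2)

  out <- tibble::tibble(
    e_estimated = e_est,
    e_measured = e_meas,
    e_difference = e_est - e_meas,
    r2_est_age = v_q / v_est,
    r2_meas_age = preset$pwv_slope^2 * v_age / v_meas,
    r2_est_meas = cov_em^2 / (v_est * v_meas)
  )
  structure(out, class = c("pwv_oracle", class(out)))
}
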