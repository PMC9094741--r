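# ggplot2 figure builders for the headline result types.

#' Estimated PWV versus age across cohorts
#'
#' Scatter of estimated PWV against chronological age for every simulated
#' cohort, with one quadratic fit per cohort — the figure that shows the
#' cohorts falling on the same age curve regardless of fitness.
#'
#' @param study A `pwv_study`, or a data frame with columns `age`,
#'   `estimated_pwv` and (optionally) `cohort`.
#' @return A ggplot object.
#' @export
plot_age_correlation <- function(study) {
  df <- if (inherits(study, "pwv_study")) {
    purrr::imap_dfr(study$records, function(rec, nm) {
      tibble::tibble(age = rec$age, estimated_pwv = rec$estimated_pwv, cohort = nm)
    })
  } else {
    d <- tibble::as_tibble(study)
    if (!"cohort" %in% names(d)) d$cohort <- "cohort"
    d
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$estimated_pwv, colour = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.7, shape = 1) +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x + I(x^2), se = FALSE, linewidth = 0.6
    ) +
    ggplot2::labs(
      x = "Age (years)", y = "Estimated PWV (m/s)", colour = NULL,
      title = "Estimated PWV is driven by age in every cohort"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_pwvagree
#' @method autoplot pwv_agreement
#' @export
autoplot.pwv_agreement <- function(object, type = c("age", "mean"), ...) {
  type <- match.arg(type)
  df <- object$data
  if (type == "age") {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$difference)) +
      ggplot2::geom_point(shape = 15) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.6) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::labs(
        x = "Age (years)", y = "Estimated - measured PWV (m/s)",
        title = sprintf(
          "Method difference grows with age (slope %.3f m/s per yr)",
          object$diff_vs_age_slope
        )
      )
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$pair_mean, .data$difference)) +
      ggplot2::geom_point(shape = 15) +
      ggplot2::geom_hline(yintercept = object$mean_difference) +
      ggplot2::geom_hline(
        yintercept = object$limits_of_agreement,
        linetype = "dashed"
      ) +
      ggplot2::labs(
        x = "Mean of methods (m/s)", y = "Estimated - measured PWV (m/s)",
        title = "Bland-Altman agreement"
      )
  }
  p + ggplot2::theme_minimal()
}

#' Autoplot methods for pwvagree result objects
#'
#' `autoplot.pwv_agreement()` draws the method difference against age
#' (default) or the classic Bland-Altman difference-vs-mean display;
#' `autoplot.entered_age_result()` draws the single-subject entered-age
#' experiment with its quadratic fit; `autoplot.waveform_bundle()` shows the
#' three synthesized channels with the ground-truth fiducials overlaid.
#'
#' @param object The result object.
#' @param type For agreements: `"age"` or `"mean"`.
#' @param ... Unused.
#' @param max_seconds For waveform bundles, how much signal to show.
#' @return A ggplot object.
#' @name autoplot_pwvagree
NULL

#' @rdname autoplot_pwvagree
#' @method autoplot entered_age_result
#' @export
autoplot.entered_age_result <- function(object, ...) {
  df <- object$measurements
  grid <- tibble::tibble(entered_age = seq(
    min(df$entered_age), max(df$entered_age),
    length.out = 200
  ))
  grid$value <- stats::predict(object$fit, grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$entered_age, .data$value)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(shape = 1, size = 2) +
    ggplot2::labs(
      x = "Entered age (years)", y = "Estimated PWV (m/s)",
      title = sprintf(
        "One subject, entered age varied: R² = %.3f", object$r_squared
      )
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_pwvagree
#' @method autoplot waveform_bundle
#' @export
autoplot.waveform_bundle <- function(object, max_seconds = 10, ...) {
  ch <- object$channels[object$channels$t <= max_seconds, ]
  long <- tidyr::pivot_longer(ch, -"t", names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("ecg", "doppler_env", "cuff"))
  truth <- object$truth
  marks <- if (!is.null(truth)) {
    tibble::tibble(
      t = c(truth$t_r, truth$t_valve, truth$t_foot),
      channel = factor(
        rep(c("ecg", "doppler_env", "cuff"), each = nrow(truth)),
        levels = levels(long$channel)
      )
    )
  } else {
    NULL
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL, title = object$subject_id) +
    ggplot2::theme_minimal()
  if (!is.null(marks)) {
    marks <- marks[marks$t <= max_seconds, ]
    p <- p + ggplot2::geom_vline(
      data = marks, ggplot2::aes(xintercept = .data$t),
      colour = "red", linetype = "dotted", linewidth = 0.3
    )
  }
  p
}
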