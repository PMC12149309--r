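#' Plot a denoising result
#'
#' Input and denoised traces stacked for visual comparison.
#'
#' @param object An `esvt_denoise` object.
#' @param window_s Optional time window (s) to display, e.g. `c(0, 10)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esvt_denoise
#' @export
autoplot.esvt_denoise <- function(object, window_s = NULL, ...) {
  df <- tibble::tibble(
    time = rep(object$denoised$time, 2),
    value = c(object$input, object$denoised$value),
    trace = rep(c("input", "denoised"), each = length(object$input))
  )
  if (!is.null(window_s)) {
    df <- dplyr::filter(df, .data$time >= window_s[1], .data$time <= window_s[2])
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ factor(trace, c("input", "denoised")), ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a grid-search heatmap
#'
#' Mean cardiac-referenced SNR over the threshold/iteration grid, with the
#' optimum marked.
#'
#' @param object An `esvt_grid` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esvt_grid
#' @export
autoplot.esvt_grid <- function(object, ...) {
  ggplot2::ggplot(
    object$snr,
    ggplot2::aes(factor(.data$iterations), factor(signif(.data$tau, 4)),
      fill = .data$snr_db
    )
  ) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point",
      x = factor(object$optimum$iterations),
      y = factor(signif(object$optimum$tau, 4)), shape = 4, size = 3
    ) +
    ggplot2::scale_fill_viridis_c(name = "SNR (dB)", option = "inferno") +
    ggplot2::labs(x = "iterations", y = "threshold tau (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark curve
#'
#' Mean SNR gain per nominal noise level for each denoising method.
#'
#' @param object An `esvt_benchmark` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot esvt_benchmark
#' @export
autoplot.esvt_benchmark <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(.data$nominal_snr_db, .data$mean_gain_db, colour = .data$method)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "nominal input SNR (dB)", y = "mean SNR gain (dB)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot heart-rate agreement
#'
#' Bland-Altman plot (default) with the bias and limits of agreement, or a
#' scatter of the paired heart rates with the identity line.
#'
#' @param object An `hr_agreement` object.
#' @param type `"bland-altman"` or `"scatter"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hr_agreement
#' @export
autoplot.hr_agreement <- function(object, type = c("bland-altman", "scatter"), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    return(
      ggplot2::ggplot(object$data, ggplot2::aes(.data$hr_b, .data$hr_a)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
        ggplot2::geom_point(alpha = 0.6) +
        ggplot2::labs(x = "ECG heart rate (bpm)", y = "BCG heart rate (bpm)") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object$data, ggplot2::aes(.data$mean_hr, .data$diff)) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(
      yintercept = c(object$loa_low, object$loa_high),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "mean of BCG and ECG heart rate (bpm)",
      y = "BCG - ECG difference (bpm)"
    ) +
    ggplot2::theme_minimal()
}
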