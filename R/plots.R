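#' Plot biodynamic magnitude curves
#'
#' Faceted magnitude-versus-frequency plot of the three biodynamic
#' responses, with free y scales (STHT is near unity while DPMI runs
#' in the thousands).
#'
#' @param object A `vb_curves` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vb_curves <- function(object, ...) {
  labs <- c(stht_mag = "STHT (-)", dpmi_mag = "DPMI (N·s/m)",
            am_mag = "AM (kg)")
  curve_magnitudes(object) |>
    tidyr::pivot_longer(-"frequency_hz",
                        names_to = "response", values_to = "magnitude") |>
    dplyr::mutate(response = factor(labs[.data$response], levels = labs)) |>
    ggplot2::ggplot(ggplot2::aes(.data$frequency_hz, .data$magnitude)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~response, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Frequency (Hz)", y = NULL,
                  title = "Biodynamic responses under vertical base excitation")
}

#' Plot a calibration convergence history
#'
#' Best objective value per Firefly-Algorithm iteration (log scale):
#' the convergence trace of the run.
#'
#' @param object A `vb_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vb_calibration <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(.data$iteration, .data$best_objective)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Iteration", y = "Best objective F",
                  title = "Firefly Algorithm convergence",
                  subtitle = paste0("seed ", object$seed, ", ",
                                    object$evaluations, " evaluations"))
}

#' Plot mode shapes
#'
#' Normalized displacement of each segment for the first few undamped
#' modes.
#'
#' @param object A `vb_modes`.
#' @param n_modes Number of lowest modes to show (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vb_modes <- function(object, n_modes = 2, ...) {
  tidy(object) |>
    dplyr::filter(.data$mode <= n_modes) |>
    dplyr::mutate(label = sprintf("mode %d (%.2f Hz)",
                                  .data$mode, .data$frequency_hz)) |>
    ggplot2::ggplot(ggplot2::aes(.data$segment, .data$amplitude,
                                 colour = .data$label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = scales_breaks_int) +
    ggplot2::labs(x = "Segment index", y = "Normalized amplitude",
                  colour = NULL, title = "Undamped mode shapes")
}

scales_breaks_int <- function(lims) seq(ceiling(lims[1]), floor(lims[2]))
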