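# ggplot2 displays for the main result types.

#' Plot a groove-width profile along the duplex
#'
#' @param grooves A [groove_widths()] tibble.
#' @return A ggplot object (major and minor widths vs base-pair level, with
#'   the canonical ideal-B major-groove width as a reference line).
#' @export
plot_groove_profile <- function(grooves) {
  long <- tidyr::pivot_longer(grooves, c("major_width", "minor_width"),
                              names_to = "groove", values_to = "width")
  long$groove <- sub("_width", "", long$groove)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$width,
                                     colour = .data$groove)) +
    ggplot2::geom_hline(yintercept = 11.7, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "base-pair level", y = "groove width (Å)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-step helical parameters
#'
#' @param steps A [step_parameters()] tibble.
#' @param parameters Which of the six parameters to show.
#' @return A faceted ggplot object.
#' @export
plot_step_parameters <- function(steps, parameters = c("twist", "roll", "rise")) {
  long <- tidyr::pivot_longer(steps, dplyr::all_of(parameters),
                              names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "step (5' to 3', strand I)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot motif-scan hits along a genome
#'
#' @param hits A [scan_motif()] tibble.
#' @return A ggplot object of score vs position, colored by strand.
#' @export
plot_motif_hits <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$start, y = .data$score,
                                     colour = .data$strand)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$start, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "position (bp, plus strand)", y = "match score",
                  colour = "strand") +
    ggplot2::theme_minimal()
}

#' Binding-isotherm display for an ITC fit
#'
#' Observed injection heats against molar ratio with the fitted model curve.
#'
#' @param object An `itc_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  obs <- object$isotherm
  fit <- object$fitted
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$molar_ratio,
                                    y = .data$heat_kcal_per_mol)) +
    ggplot2::geom_point(shape = 15) +
    ggplot2::geom_line(data = fit, colour = "red3") +
    ggplot2::labs(x = "molar ratio (duplex / dimer)",
                  y = "kcal per mole of injectant",
                  title = paste("ITC", object$model, "fit")) +
    ggplot2::theme_minimal()
}
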