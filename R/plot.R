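#' Plot a force-relaxation curve
#'
#' @param object A `force_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$force_N)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "time (s)", y = "reaction force (N)",
                  title = sprintf("Indentation stress relaxation (%s)",
                                  attr(object, "provenance") %||% "")) +
    ggplot2::theme_minimal()
}

#' Overlay a fitted curve on its measurement
#'
#' @param object An `frpe_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frpe_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(object$measured[c("time_s", "force_N")]),
                  which = "measured"),
    dplyr::mutate(tibble::as_tibble(object$fitted_curve[c("time_s", "force_N")]),
                  which = "fitted"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$force_N,
                                   colour = .data$which)) +
    ggplot2::geom_line(data = ~dplyr::filter(.x, .data$which == "fitted")) +
    ggplot2::geom_point(data = ~dplyr::filter(.x, .data$which == "measured"),
                        size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(measured = "grey40",
                                            fitted = "#d95f02")) +
    ggplot2::labs(x = "time (s)", y = "force (N)",
                  subtitle = sprintf("NMSE %.3g, R² %.3f",
                                     object$nmse, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter-recovery study
#'
#' Fitted-versus-true scatter per parameter, with the identity line.
#'
#' @param report A [recovery_study()] report.
#' @return A ggplot.
#' @export
plot_recovery_study <- function(report) {
  nm <- c("E_f", "E_nf", "k_0", "M")
  long <- dplyr::bind_rows(lapply(nm, function(k)
    tibble::tibble(param = k,
                   truth = report[[paste0(k, "_true")]],
                   fitted = report[[paste0(k, "_fit")]])))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$truth, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(colour = "#1b9e77") +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = "true value", y = "fitted value") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
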