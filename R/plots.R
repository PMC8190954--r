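#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of absolute solubility errors
#'
#' One bar per compound x hydration model showing
#' `|log S0 (calc) - log S0 (expt)|`, the standard at-a-glance comparison
#' of hydration models across compounds.
#'
#' @param result a `solubility_result` tibble with experimental
#'   references.
#' @return A ggplot object.
#' @examples
#' plot_solubility_errors(reference_solubility())
#' @export
plot_solubility_errors <- function(result) {
  df <- dplyr::filter(tidy(result), !is.na(.data$error))
  if (nrow(df) == 0) {
    rlang::abort("no experimental references to plot errors against")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compound,
                                   y = abs(.data$error),
                                   fill = .data$hydration_model)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = expression("|" * Delta * log ~ S[0] * "|"),
                  fill = "hydration model") +
    ggplot2::theme_minimal()
}

#' @rdname plot_solubility_errors
#' @param object a `solubility_result`.
#' @param ... unused.
#' @method autoplot solubility_result
#' @export
autoplot.solubility_result <- function(object, ...) {
  plot_solubility_errors(object)
}

#' Stick plot of a mode spectrum
#'
#' @param object a [mode_spectrum()].
#' @param ... unused.
#' @return A ggplot object with frequency on x, weight as stick height,
#'   colored by mode character.
#' @method autoplot mode_spectrum
#' @export
autoplot.mode_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$frequency, xend = .data$frequency,
                               y = 0, yend = .data$weight,
                               colour = .data$character)) +
    ggplot2::geom_segment(linewidth = 0.6) +
    ggplot2::labs(x = expression(nu ~ (cm^-1)), y = "weight",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
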