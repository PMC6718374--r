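#' Plot a Fermi deconvolution fit
#'
#' Overlays the measured tissue curve, the fitted model curve and the
#' (rescaled) AIF.
#'
#' @param object A `fermi_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fermi_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble(time = object$tissue$time, value = object$tissue$value, curve = "tissue"),
    tibble(time = object$fitted_curve$time, value = object$fitted_curve$value,
           curve = "model"),
    tibble(time = object$aif$time, value = object$aif$value, curve = "AIF"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = curve_unit(object$tissue),
                  title = sprintf("Fermi deconvolution: MBF %.2f mL/g/min", object$mbf))
}

#' Plot a one-tissue-compartment fit
#'
#' Frame-mean tissue activity with the fitted model and the reconstructed
#' arterial input.
#'
#' @param object A `onetc_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.onetc_fit <- function(object, ...) {
  mid <- function(tac) tac$start + tac$duration / 2
  df <- dplyr::bind_rows(
    tibble(time = mid(object$tissue_tac), value = object$tissue_tac$activity,
           curve = "tissue"),
    tibble(time = mid(object$fitted_tac), value = object$fitted_tac$activity,
           curve = "model"),
    tibble(time = mid(object$aif_tac), value = object$aif_tac$activity,
           curve = "AIF"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "activity (kBq/mL)",
                  title = sprintf("1TC fit: MBF %.2f mL/g/min, k2 %.2f min^-1",
                                  object$mbf, object$params$k2))
}

#' Bland-Altman plot of an agreement report
#'
#' Paired differences against pair means, with the bias and 95% limits of
#' agreement as dashed lines.
#'
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_report <- function(object, ...) {
  p <- attr(object, "pairs")
  df <- tibble(mean = (p$x + p$y) / 2, diff = p$x - p$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(object$bias, object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of pair (mL/g/min)", y = "difference (mL/g/min)",
                  title = sprintf("Bland-Altman: bias %.2f [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high))
}
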