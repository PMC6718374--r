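#' Tidy a Fermi deconvolution fit
#'
#' @param x A `fermi_fit` from [fit_fermi()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: a one-row tibble with `mbf`, `rss`, `n_iter`,
#'   `converged`, `calibration`.
#' @export
tidy.fermi_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidy.fermi_fit
#' @export
glance.fermi_fit <- function(x, ...) {
  tibble(mbf = x$mbf, rss = x$rss, n_iter = x$n_iter,
         converged = x$converged, calibration = x$calibration)
}

#' Tidy a one-tissue-compartment fit
#'
#' @param x A `onetc_fit` from [fit_1tc()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; `glance()`: a one-row tibble
#'   with `mbf`, `rss`, `fit_window`, `n_iter`, `converged`,
#'   `calibration`.
#' @export
tidy.onetc_fit <- function(x, ...) {
  tidyr::pivot_longer(x$params, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidy.onetc_fit
#' @export
glance.onetc_fit <- function(x, ...) {
  tibble(mbf = x$mbf, rss = x$rss, fit_window = x$fit_window,
         n_iter = x$n_iter, converged = x$converged,
         calibration = x$calibration)
}

#' @export
tidy.agreement_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @export
glance.agreement_report <- function(x, ...) as_tibble(x)
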