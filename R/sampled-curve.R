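#' Sampled time curves
#'
#' A `sampled_curve` is the universal carrier for time-resolved ROI data in
#' perfquant: arterial input functions, myocardial tissue curves, MR signal
#' dynamics and fine-grid tracer activity curves. It is an ordinary tibble
#' with columns `time` (seconds since the start of the protocol clock,
#' strictly increasing) and `value`, plus a declared unit, so it composes
#' with dplyr/tidyr verbs; perfquant functions re-validate it on entry.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param value Numeric vector of samples, same length as `time`.
#' @param unit Unit of `value`: one of `"a.u."` (signal), `"mmol/L"`
#'   (gadolinium concentration), `"kBq/mL"` (activity concentration) or
#'   `"unitless"`.
#' @return A tibble of class `sampled_curve` with columns `time` and `value`
#'   and a `unit` attribute.
#' @examples
#' sampled_curve(0:9, dgamma(0:9, 3, 1), unit = "mmol/L")
#' @export
sampled_curve <- function(time, value, unit = c("a.u.", "mmol/L", "kBq/mL", "unitless")) {
  unit <- match.arg(unit)
  out <- tibble(time = as.numeric(time), value = as.numeric(value))
  out <- structure(out, class = c("sampled_curve", class(tibble())), unit = unit)
  validate_sampled_curve(out)
  out
}

#' @rdname sampled_curve
#' @param x A data frame with columns `time` and `value`.
#' @export
as_sampled_curve <- function(x, unit = NULL) {
  if (inherits(x, "sampled_curve") && is.null(unit)) {
    validate_sampled_curve(x)
    return(x)
  }
  if (!all(c("time", "value") %in% names(x))) {
    abort("`x` must have columns `time` and `value`.")
  }
  sampled_curve(x$time, x$value, unit = unit %||% attr(x, "unit") %||% "unitless")
}

#' @export
curve_unit <- function(curve) attr(curve, "unit") %||% "unitless"

validate_sampled_curve <- function(curve, arg = "curve") {
  if (!all(c("time", "value") %in% names(curve))) {
    abort(sprintf("`%s` must have columns `time` and `value`.", arg))
  }
  if (nrow(curve) < 2) {
    abort(sprintf("`%s` must have at least 2 samples.", arg))
  }
  dt <- diff(curve$time)
  if (any(!is.finite(curve$time)) || any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1
    abort(sprintf("`%s`: times must be strictly increasing (first violation at row %d).",
                  arg, bad))
  }
  if (any(!is.finite(curve$value))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(curve)
}

# rebuild class/attrs after dplyr operations stripped them
restore_curve <- function(df, template) {
  sampled_curve(df$time, df$value, unit = curve_unit(template))
}

#' Trapezoidal integral of a curve
#'
#' @param curve A [sampled_curve()] (or any data frame with `time`, `value`).
#' @return The trapezoidal-rule integral of `value` over `time`, in
#'   `unit * s`.
#' @export
curve_integral <- function(curve) {
  trapz(curve$time, curve$value)
}

trapz <- function(t, y) {
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

is_uniform_grid <- function(t, tol = 1e-8) {
  dt <- diff(t)
  diff(range(dt)) <= tol * mean(dt)
}

# resample a curve onto a uniform grid (linear interpolation); no-op if uniform
resample_uniform <- function(curve, dt = NULL) {
  if (is.null(dt) && is_uniform_grid(curve$time)) return(curve)
  dt <- dt %||% min(diff(curve$time))
  tg <- seq(curve$time[1], curve$time[nrow(curve)], by = dt)
  sampled_curve(tg, approx(curve$time, curve$value, tg)$y, unit = curve_unit(curve))
}

#' @export
print.sampled_curve <- function(x, ...) {
  cat(sprintf("# A sampled_curve: %d samples, %.6g-%.6g s, unit %s\n",
              nrow(x), x$time[1], x$time[nrow(x)], curve_unit(x)))
  NextMethod()
}

#' @export
autoplot.sampled_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(...) +
    ggplot2::labs(x = "time (s)", y = curve_unit(object))
}
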