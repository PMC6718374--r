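#' PET frame schemes and framed time-activity curves
#'
#' A `frame_scheme` is a tibble of contiguous, non-overlapping PET time
#' frames (`start`, `duration`, seconds). A `framed_tac` carries a frame
#' scheme plus the frame-mean activity concentration of a region, the
#' discrete acquisition grid of the PET side of the pipeline.
#'
#' @param start Frame start times (s); must satisfy
#'   `start[i+1] == start[i] + duration[i]`.
#' @param duration Frame durations (s), all positive.
#' @return `frame_scheme()`: a tibble of class `frame_scheme` with columns
#'   `start`, `duration`.
#' @examples
#' default_frame_scheme()      # 60 x 3 s then 8 x 15 s, 300 s total
#' @export
frame_scheme <- function(start, duration) {
  out <- tibble(start = as.numeric(start), duration = as.numeric(duration))
  if (nrow(out) < 1 || any(out$duration <= 0)) {
    abort("frame durations must all be positive.")
  }
  if (nrow(out) > 1) {
    gap <- abs(out$start[-1] - (out$start[-nrow(out)] + out$duration[-nrow(out)]))
    if (any(gap > 1e-9)) {
      abort(sprintf("frames must be contiguous; first gap/overlap after frame %d.",
                    which(gap > 1e-9)[1]))
    }
  }
  structure(out, class = c("frame_scheme", class(tibble())))
}

#' @rdname frame_scheme
#' @param injection_time Protocol-clock time (s) at which the tracer is
#'   injected; the scheme starts there.
#' @details `default_frame_scheme()` is the dynamic 13N-ammonia binning used
#'   throughout: 60 frames of 3 s followed by 8 frames of 15 s (68 frames,
#'   300 s).
#' @export
default_frame_scheme <- function(injection_time = 0) {
  dur <- c(rep(3, 60), rep(15, 8))
  frame_scheme(injection_time + cumsum(c(0, dur[-length(dur)])), dur)
}

#' @rdname frame_scheme
#' @param scheme A [frame_scheme()].
#' @param activity Frame-mean activity concentration (kBq/mL), one per frame.
#' @param decay_corrected Logical flag; `FALSE` for as-measured activities.
#' @param reference_time Decay reference time on the protocol clock (s),
#'   conventionally the injection time.
#' @return `framed_tac()`: a tibble of class `framed_tac` with columns
#'   `start`, `duration`, `activity` and attributes `decay_corrected`,
#'   `reference_time`.
#' @export
framed_tac <- function(scheme, activity, decay_corrected = FALSE,
                       reference_time = scheme$start[1]) {
  scheme <- frame_scheme(scheme$start, scheme$duration)
  if (length(activity) != nrow(scheme)) {
    abort("`activity` must have one value per frame.")
  }
  out <- tibble(start = scheme$start, duration = scheme$duration,
                activity = as.numeric(activity))
  structure(out, class = c("framed_tac", class(tibble())),
            decay_corrected = isTRUE(decay_corrected),
            reference_time = reference_time)
}

tac_scheme <- function(tac) frame_scheme(tac$start, tac$duration)

#' @export
is_decay_corrected <- function(tac) isTRUE(attr(tac, "decay_corrected"))

#' Bin a fine-sampled activity curve into PET frames
#'
#' Each frame mean is the time-average of the (linearly interpolated) fine
#' curve over `[start, start + duration)`, computed by exact trapezoidal
#' integration of the piecewise-linear interpolant.
#'
#' @param fine_curve A [sampled_curve()] spanning the whole scheme.
#' @param scheme A [frame_scheme()].
#' @param decay_corrected Flag recorded on the result (whether `fine_curve`
#'   was already corrected for physical decay).
#' @param reference_time Decay reference time (s); defaults to the scheme
#'   start.
#' @return A [framed_tac()].
#' @export
bin_frames <- function(fine_curve, scheme, decay_corrected = FALSE,
                       reference_time = scheme$start[1]) {
  fine_curve <- as_sampled_curve(fine_curve)
  t0 <- scheme$start[1]
  t1 <- scheme$start[nrow(scheme)] + scheme$duration[nrow(scheme)]
  if (fine_curve$time[1] > t0 + 1e-9 ||
      fine_curve$time[nrow(fine_curve)] < t1 - 1e-9) {
    abort(sprintf("fine curve [%.6g, %.6g] s does not cover the frame scheme [%.6g, %.6g] s.",
                  fine_curve$time[1], fine_curve$time[nrow(fine_curve)], t0, t1))
  }
  # cumulative integral of the piecewise-linear interpolant, evaluated at
  # frame boundaries; frame mean = integral difference / duration
  tt <- fine_curve$time
  vv <- fine_curve$value
  cum <- c(0, cumsum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2))
  cum_at <- function(x) {
    i <- findInterval(x, tt, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1), length(tt) - 1)
    h <- x - tt[i]
    slope <- (vv[i + 1] - vv[i]) / (tt[i + 1] - tt[i])
    cum[i] + vv[i] * h + slope * h^2 / 2
  }
  lo <- cum_at(scheme$start)
  hi <- cum_at(scheme$start + scheme$duration)
  framed_tac(scheme, (hi - lo) / scheme$duration,
             decay_corrected = decay_corrected, reference_time = reference_time)
}

#' Correct a PET time-activity curve for physical decay
#'
#' Multiplies each frame mean by the exact frame-average decay-correction
#' factor \eqn{f = \lambda \Delta t / (e^{-\lambda t_1}(1 - e^{-\lambda
#' \Delta t}))} with \eqn{\lambda = \ln 2 / T_{1/2}}, \eqn{t_1} the frame
#' start relative to the reference time and \eqn{\Delta t} the duration.
#' This is the average of the decay factor over the frame, not its midpoint
#' value, so a truly constant source measured under decay is restored
#' exactly.
#'
#' @param tac A [framed_tac()] with `decay_corrected = FALSE`.
#' @param half_life Radionuclide half-life in minutes. The default is the
#'   13N half-life, 9.96 min.
#' @param reference_time Decay reference time (s); defaults to the value
#'   recorded on `tac` (conventionally the injection time).
#' @return The corrected [framed_tac()] with `decay_corrected = TRUE`.
#' @export
decay_correct <- function(tac, half_life = 9.96, reference_time = NULL) {
  if (is_decay_corrected(tac)) {
    abort("`tac` is already decay-corrected; refusing to correct twice.")
  }
  if (half_life <= 0) abort("`half_life` must be positive (minutes).")
  reference_time <- reference_time %||% attr(tac, "reference_time") %||% tac$start[1]
  lam <- log(2) / (half_life * 60)          # s^-1
  t1 <- tac$start - reference_time
  dt <- tac$duration
  f <- lam * dt / (exp(-lam * t1) * -expm1(-lam * dt))
  framed_tac(tac_scheme(tac), tac$activity * f,
             decay_corrected = TRUE, reference_time = reference_time)
}

#' @export
print.framed_tac <- function(x, ...) {
  cat(sprintf("# A framed_tac: %d frames, %.6g-%.6g s, decay_corrected=%s\n",
              nrow(x), x$start[1], x$start[nrow(x)] + x$duration[nrow(x)],
              is_decay_corrected(x)))
  NextMethod()
}

#' @export
autoplot.framed_tac <- function(object, ...) {
  df <- as_tibble(object)
  df$mid <- df$start + df$duration / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$activity)) +
    ggplot2::geom_point(...) +
    ggplot2::geom_step(ggplot2::aes(x = .data$start), alpha = 0.4) +
    ggplot2::labs(x = "time (s)", y = "activity (kBq/mL)")
}
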