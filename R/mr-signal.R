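#' MR acquisition parameters for the saturation-recovery FLASH signal model
#'
#' @param ti_ms Saturation-recovery time TI (ms).
#' @param tr_ms Repetition time TR (ms); carried as metadata (the analytic
#'   signal model does not use the readout train).
#' @param flip_deg Flip angle (degrees), in (0, 90].
#' @param t10_ms Pre-contrast longitudinal relaxation time T1 (ms).
#' @param r1_relaxivity Contrast-agent relaxivity (L mmol^-1 s^-1);
#'   gadobutrol at 3 T defaults to 5.0.
#' @param m0 Equilibrium signal scale (a.u.).
#' @param n_dynamics,n_baseline Number of dynamics and of pre-contrast
#'   baseline dynamics.
#' @param dynamic_interval Seconds between dynamics.
#' @return A list of class `mr_protocol`.
#' @details `mr_protocol_phantom()` is the phantom acquisition (TI 100 ms,
#'   TR 1.9 ms, flip 10 degrees, 240 dynamics, long saline T1 of 3000 ms);
#'   `mr_protocol_volunteer()` is the in vivo stress protocol (TI 115 ms,
#'   TR 1.5 ms, flip 14 degrees, 120 dynamics, 8 baseline dynamics, blood
#'   T10 1900 ms).
#' @export
mr_protocol <- function(ti_ms = 100, tr_ms = 1.9, flip_deg = 10,
                        t10_ms = 3000, r1_relaxivity = 5.0, m0 = 1000,
                        n_dynamics = 240, n_baseline = 8,
                        dynamic_interval = 1) {
  if (ti_ms <= 0 || tr_ms <= 0 || t10_ms <= 0) {
    abort("`ti_ms`, `tr_ms` and `t10_ms` must be positive.")
  }
  if (flip_deg <= 0 || flip_deg > 90) abort("`flip_deg` must be in (0, 90].")
  if (n_baseline >= n_dynamics) abort("`n_baseline` must be < `n_dynamics`.")
  structure(as.list(environment()), class = "mr_protocol")
}

#' @rdname mr_protocol
#' @export
mr_protocol_phantom <- function() mr_protocol()

#' @rdname mr_protocol
#' @export
mr_protocol_volunteer <- function(t10_ms = 1900) {
  mr_protocol(ti_ms = 115, tr_ms = 1.5, flip_deg = 14, t10_ms = t10_ms,
              n_dynamics = 120, n_baseline = 8)
}

#' Saturation-recovery FLASH signal model
#'
#' Analytic forward model \eqn{S = M_0 \sin\alpha (1 - e^{-TI \cdot R_1})}
#' with \eqn{R_1 = 1/T_{10} + r_1 c} (s^-1). Strictly increasing in
#' concentration, with the saturation ceiling \eqn{M_0 \sin\alpha} as
#' \eqn{c \to \infty} — the non-linear signal-concentration relationship
#' that dual-bolus AIF measurement works around.
#'
#' @param conc Gadolinium concentration(s), mmol/L, all >= 0.
#' @param protocol An [mr_protocol()].
#' @return Signal in a.u., same length as `conc`.
#' @export
srflash_signal <- function(conc, protocol = mr_protocol_phantom()) {
  if (any(conc < 0)) abort("`conc` must be non-negative.")
  r1 <- 1 / (protocol$t10_ms / 1000) + protocol$r1_relaxivity * conc
  protocol$m0 * sin(protocol$flip_deg * pi / 180) *
    (1 - exp(-(protocol$ti_ms / 1000) * r1))
}

#' Signal-concentration lookup table
#'
#' Tabulates the forward signal model on a uniform concentration grid
#' `[0, conc_max]`, the invertible lookup used to convert measured signal
#' back to gadolinium concentration.
#'
#' @param protocol An [mr_protocol()].
#' @param conc_max Largest tabulated concentration (mmol/L, > 0).
#' @param n_points Number of grid points (>= 2).
#' @return A tibble of class `signal_lut` with columns `conc`, `signal`.
#' @export
build_lut <- function(protocol, conc_max = 10, n_points = 4096) {
  if (conc_max <= 0) abort("`conc_max` must be positive.")
  if (n_points < 2) abort("`n_points` must be >= 2.")
  conc <- seq(0, conc_max, length.out = n_points)
  signal <- srflash_signal(conc, protocol)
  if (any(diff(signal) <= 0)) {
    abort("tabulated signal is not strictly increasing; the protocol is degenerate.")
  }
  structure(tibble(conc = conc, signal = signal),
            class = c("signal_lut", class(tibble())))
}

#' Convert an MR signal curve to gadolinium concentration
#'
#' Rescales the lookup table so its zero-concentration signal matches
#' `baseline_signal` (a proportional M0 calibration), then inverts the
#' strictly monotone table by linear interpolation. Samples below the
#' baseline clamp to concentration 0; their count is reported in the
#' `n_clamped` attribute of the result.
#'
#' @param curve MR signal [sampled_curve()] (a.u.).
#' @param lut A [build_lut()] table.
#' @param baseline_signal Measured pre-contrast signal (a.u.), e.g. the
#'   mean over the baseline dynamics.
#' @return A [sampled_curve()] in mmol/L with attribute `n_clamped`.
#' @export
signal_to_concentration <- function(curve, lut, baseline_signal) {
  curve <- as_sampled_curve(curve)
  if (baseline_signal <= 0) abort("`baseline_signal` must be positive.")
  scale <- baseline_signal / lut$signal[1]
  sig <- lut$signal * scale
  over <- curve$value > max(sig) * (1 + 1e-12)
  if (any(over)) {
    abort(sprintf("signal exceeds the rescaled LUT ceiling at t = %s s; increase `conc_max`.",
                  paste(signif(curve$time[over], 6), collapse = ", ")))
  }
  conc <- approx(sig, lut$conc, pmax(curve$value, sig[1]), rule = 2)$y
  out <- sampled_curve(curve$time, pmax(conc, 0), unit = "mmol/L")
  attr(out, "n_clamped") <- sum(curve$value < sig[1])
  out
}

#' Subtract the pre-contrast baseline from a dynamic curve
#'
#' @param dynamics A [sampled_curve()] of signal dynamics.
#' @param n_baseline Number of leading pre-contrast samples whose mean is
#'   subtracted (>= 1, < curve length).
#' @return The baseline-corrected [sampled_curve()] (idempotent up to the
#'   noise mean).
#' @export
baseline_correct <- function(dynamics, n_baseline = 8) {
  dynamics <- as_sampled_curve(dynamics)
  if (n_baseline < 1 || n_baseline >= nrow(dynamics)) {
    abort("`n_baseline` must be >= 1 and smaller than the curve length.")
  }
  sampled_curve(dynamics$time,
                dynamics$value - mean(dynamics$value[seq_len(n_baseline)]),
                unit = curve_unit(dynamics))
}

# first sample exceeding `frac` of the curve maximum within the window;
# ties broken by the earliest sample
detect_foot <- function(curve, frac = 0.05, window = Inf) {
  inwin <- curve$time <= curve$time[1] + window
  pk <- max(curve$value[inwin])
  if (!is.finite(pk) || pk <= 0) {
    abort("no detectable bolus foot: curve has no positive peak in the window.")
  }
  idx <- which(inwin & curve$value > frac * pk)[1]
  if (is.na(idx)) abort("no detectable bolus foot within the window.")
  curve$time[idx]
}

#' Assemble the neat-bolus surrogate AIF from the dilute-bolus AIF
#'
#' Scales the dilute AIF by the contrast dose ratio and time-shifts it
#' (by a whole number of samples) so that its bolus foot — the first
#' sample exceeding 5% of the peak within `foot_window` — lands at
#' `neat_arrival`. When `neat_arrival` is the detected dilute foot plus
#' the known inter-bolus injection interval, the surrogate aligns exactly
#' with the neat bolus, which is how the dual-bolus protocol is meant to
#' be used.
#'
#' @param dilute_aif Baseline-corrected dilute-bolus AIF
#'   ([sampled_curve()]).
#' @param dose_ratio Neat:dilute dose ratio (> 0).
#' @param neat_arrival Target foot time for the surrogate (s).
#' @param foot_window Seconds from curve start within which to search for
#'   the foot.
#' @param foot_frac Foot threshold as a fraction of peak.
#' @return The surrogate AIF [sampled_curve()] on the same grid (zeros
#'   shifted in from the start or end).
#' @export
assemble_dual_bolus_aif <- function(dilute_aif, dose_ratio = 10, neat_arrival,
                                    foot_window = Inf, foot_frac = 0.05) {
  dilute_aif <- as_sampled_curve(dilute_aif)
  if (dose_ratio <= 0) abort("`dose_ratio` must be positive.")
  foot <- detect_foot(dilute_aif, frac = foot_frac, window = foot_window)
  dt <- median(diff(dilute_aif$time))
  shift <- round((neat_arrival - foot) / dt)
  v <- dilute_aif$value * dose_ratio
  n <- length(v)
  if (shift >= 0) {
    v <- c(rep(0, min(shift, n)), v)[seq_len(n)]
  } else {
    v <- c(v[-seq_len(min(-shift, n))], rep(0, min(-shift, n)))
  }
  sampled_curve(dilute_aif$time, v, unit = curve_unit(dilute_aif))
}

#' Scale the AIF so its time-integral matches the myocardial curve
#'
#' The phantom-mode saturation workaround: with complete washout the
#' well-mixed compartment conserves indicator, so the true AIF and tissue
#' curves have equal time-integrals and rescaling the measured AIF to
#' \eqn{\int myo / \int aif} (trapezoidal integrals on the common clock)
#' restores the AIF scale without knowing native T1. Idempotent, and
#' invariant to any prior positive scaling of the AIF.
#'
#' @param aif,myo [sampled_curve()]s on a common clock.
#' @return The rescaled AIF.
#' @export
normalize_aif_integral <- function(aif, myo) {
  aif <- as_sampled_curve(aif)
  myo <- as_sampled_curve(myo)
  ia <- curve_integral(aif)
  if (ia == 0) abort("`aif` has zero time-integral; cannot normalize.")
  sampled_curve(aif$time, aif$value * curve_integral(myo) / ia,
                unit = curve_unit(aif))
}

#' Fit a gamma-variate bolus model to a measured first-pass curve
#'
#' Parametric denoising of a measured AIF: fits
#' \eqn{g(t) = A ((t-t_a)/(\alpha\beta))^\alpha e^{\alpha - (t-t_a)/\beta}}
#' by bounded Levenberg-Marquardt least squares, with starts taken from the
#' curve's peak, foot and time-to-peak.
#'
#' @param curve A baseline-corrected [sampled_curve()].
#' @return A list with `params` (tibble: peak, arrival, alpha, beta),
#'   `fitted` (the smoothed [sampled_curve()]), `rss` and `converged`.
#' @export
fit_gamma_variate <- function(curve) {
  curve <- as_sampled_curve(curve)
  y <- curve$value
  ts <- curve$time
  pk <- max(y)
  if (pk <= 0) abort("curve has no positive peak; cannot fit a bolus model.")
  tp <- ts[which.max(y)]
  foot0 <- detect_foot(curve)
  st <- c(pk, foot0, 3, max((tp - foot0) / 3, 0.5))
  g <- function(p) p[1] * gamma_variate(ts, p[2], p[3], p[4])
  fit <- minpack.lm::nls.lm(
    par = st, lower = c(0, ts[1], 0.5, 0.2), upper = c(10 * pk, max(ts), 20, 60),
    fn = function(p) y - g(p),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  list(params = tibble(peak = fit$par[1], arrival = fit$par[2],
                       alpha = fit$par[3], beta = fit$par[4]),
       fitted = sampled_curve(ts, g(fit$par), unit = curve_unit(curve)),
       rss = sum(fit$fvec^2),
       converged = fit$info %in% 1:4)
}
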