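#' Bolus specification for the digital phantom
#'
#' First-pass boluses are modelled as peak-normalized gamma-variate curves:
#' a unit-dose bolus reaches a maximum of 1 at `arrival_time +
#' shape_alpha * shape_beta` seconds.
#'
#' @param dose Relative bolus amount (unitless; the neat bolus is 1).
#' @param arrival_time Bolus onset on the protocol clock (s).
#' @param shape_alpha Gamma-variate shape (unitless, > 0).
#' @param shape_beta Gamma-variate time scale (s, > 0).
#' @return A one-row tibble describing the bolus.
#' @export
bolus_spec <- function(dose, arrival_time, shape_alpha = 3, shape_beta = 4) {
  if (dose < 0) abort("`dose` must be >= 0.")
  if (shape_alpha <= 0 || shape_beta <= 0) {
    abort("`shape_alpha` and `shape_beta` must be positive.")
  }
  tibble(dose = dose, arrival_time = arrival_time,
         shape_alpha = shape_alpha, shape_beta = shape_beta)
}

gamma_variate <- function(t, arrival, alpha, beta) {
  x <- t - arrival
  out <- numeric(length(t))
  pos <- x > 0
  out[pos] <- (x[pos] / (alpha * beta))^alpha * exp(alpha - x[pos] / beta)
  out
}

#' Generate an arterial input function from a set of boluses
#'
#' Sums dose-scaled, peak-normalized gamma-variate curves on a time grid.
#' The result is linear in dose, so a dilute:neat pair with dose ratio
#' 0.1:1 yields a dilute peak exactly one tenth of the neat peak.
#'
#' @param boluses A tibble of boluses, e.g. built by binding
#'   [bolus_spec()] rows. An empty tibble (or `NULL`) yields an all-zero
#'   curve.
#' @param time_grid Strictly increasing sample times (s).
#' @param unit Unit of the generated curve.
#' @return A [sampled_curve()].
#' @examples
#' tg <- seq(0, 60, by = 0.5)
#' aif <- generate_aif(bolus_spec(1, arrival_time = 10), tg, unit = "mmol/L")
#' tg[which.max(aif$value)]   # gamma-variate mode at arrival + alpha * beta
#' @export
generate_aif <- function(boluses, time_grid, unit = "mmol/L") {
  if (any(diff(time_grid) <= 0)) abort("`time_grid` must be strictly increasing.")
  value <- numeric(length(time_grid))
  if (!is.null(boluses) && nrow(boluses) > 0) {
    for (i in seq_len(nrow(boluses))) {
      b <- boluses[i, ]
      value <- value + b$dose *
        gamma_variate(time_grid, b$arrival_time, b$shape_alpha, b$shape_beta)
    }
  }
  sampled_curve(time_grid, value, unit = unit)
}

# y(t) = int_0^t x(u) exp(-k(t-u)) du on a uniform grid, exact for a
# piecewise-linear x (integrates the exponential kernel against each linear
# segment in closed form, accumulated as a first-order recursion)
exp_convolve <- function(k, t, x) {
  h <- t[2] - t[1]
  e <- exp(-k * h)
  n <- length(x)
  a <- x[-n]
  b <- (x[-1] - x[-n]) / h
  g <- a * (1 - e) / k + b * (h - (1 - e) / k) / k
  as.numeric(stats::filter(c(0, g), e, method = "recursive"))
}

#' Simulate the well-mixed myocardial compartment of the perfusion phantom
#'
#' Integrates the single well-mixed compartment
#' \eqn{dC_m/dt = (Q/V_d)(C_a - C_m)} with \eqn{Q = flow \times
#' tissue\_mass} (mL/min), i.e.
#' \eqn{C_m(t) = (Q/V_d)\int_0^t C_a(u) e^{-(Q/V_d)(t-u)} du},
#' evaluated on the AIF grid. The exponential kernel is integrated exactly
#' against the piecewise-linear interpolant of \eqn{C_a}, so the simulator
#' contributes no rectangle-rule bias at 1-s sampling.
#'
#' @param aif Arterial input [sampled_curve()] on a uniform grid (a
#'   non-uniform grid is resampled to its smallest spacing).
#' @param flow Perfusion rate in mL/g/min (> 0).
#' @param dispersion_volume Mixing volume \eqn{V_d} at the tissue sampling
#'   site (mL, > 0).
#' @param tissue_mass Tissue-equivalent mass of the compartment (g, > 0);
#'   converts mL/min to mL/g/min.
#' @return A [sampled_curve()] with the same unit and grid as `aif`.
#' @export
simulate_tissue_curve <- function(aif, flow, dispersion_volume = 15, tissue_mass = 45) {
  aif <- as_sampled_curve(aif)
  if (flow <= 0 || dispersion_volume <= 0 || tissue_mass <= 0) {
    abort("`flow`, `dispersion_volume` and `tissue_mass` must be positive.")
  }
  grid <- aif$time
  res <- resample_uniform(aif)
  k <- flow * tissue_mass / dispersion_volume / 60   # s^-1
  cm <- k * exp_convolve(k, res$time, res$value)
  if (length(res$time) != length(grid)) {
    cm <- approx(res$time, cm, grid)$y
  }
  sampled_curve(grid, cm, unit = curve_unit(aif))
}

#' Digital perfusion phantom configuration
#'
#' Bundles the ground-truth flow, compartment geometry, injection protocol,
#' MR acquisition, PET binning and noise model of one phantom run. Defaults
#' reproduce the dual-bolus phantom protocol: heart rate 60 (one MR dynamic
#' per second), 240 dynamics, a dilute bolus (dose ratio 1:10) 120 s before
#' the neat bolus, tracer co-injected with the neat bolus, and PET frames
#' of 60 x 3 s + 8 x 15 s from injection.
#'
#' @param flow Ground-truth perfusion (mL/g/min).
#' @param dispersion_volume,tissue_mass Compartment geometry; see
#'   [simulate_tissue_curve()]. `tissue_mass / dispersion_volume` also sets
#'   the washout rate `flow * mass / V_d` (min^-1).
#' @param heart_rate Beats/min; the MR dynamic interval is `60/heart_rate` s.
#' @param interbolus_delay Seconds between dilute and neat bolus arrival.
#' @param n_dynamics Number of MR dynamics.
#' @param dilute_arrival Arrival time of the dilute bolus (s).
#' @param dose_ratio Neat:dilute contrast dose ratio.
#' @param peak_conc Arterial peak gadolinium concentration of the neat
#'   bolus (mmol/L).
#' @param pet_peak_activity Arterial peak activity of the tracer bolus
#'   (kBq/mL).
#' @param shape_alpha,shape_beta Gamma-variate bolus shape.
#' @param half_life Tracer half-life (min); 13N by default.
#' @param mr_protocol MR signal model parameters, see [mr_protocol()].
#' @param noise_mr_sigma Additive Gaussian noise sd on MR signal (a.u.);
#'   0 disables.
#' @param noise_pet_cv Multiplicative Gaussian noise on PET frame means;
#'   the per-frame cv is `noise_pet_cv / sqrt(duration_s)`, mimicking count
#'   statistics. 0 disables.
#' @param seed Integer seed driving all noise draws (reproducibility
#'   contract); `NULL` leaves the RNG state alone.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(flow,
                           dispersion_volume = 15,
                           tissue_mass = 45,
                           heart_rate = 60,
                           interbolus_delay = 120,
                           n_dynamics = 240,
                           dilute_arrival = 12,
                           dose_ratio = 10,
                           peak_conc = 0.3,
                           pet_peak_activity = 100,
                           shape_alpha = 3,
                           shape_beta = 4,
                           half_life = 9.96,
                           mr_protocol = mr_protocol_phantom(),
                           noise_mr_sigma = 0.05,
                           noise_pet_cv = 0.05,
                           seed = NULL) {
  cfg <- as.list(environment())
  with(cfg, {
    if (flow <= 0) abort("`flow` must be positive.")
    if (dispersion_volume <= 0 || tissue_mass <= 0) {
      abort("`dispersion_volume` and `tissue_mass` must be positive.")
    }
    if (heart_rate <= 0) abort("`heart_rate` must be positive.")
    if (interbolus_delay < 0) abort("`interbolus_delay` must be >= 0.")
  })
  structure(cfg, class = "phantom_config")
}

#' Simulate one dual-bolus, dual-tracer phantom run
#'
#' Generates, on a common protocol clock: (i) ground-truth gadolinium
#' concentration curves for the arterial input (dilute bolus, then a neat
#' bolus `interbolus_delay` later, dose ratio per config) and the
#' well-mixed myocardial compartment; (ii) MR signal dynamics by applying
#' the saturation-recovery FLASH signal model at one dynamic per heartbeat;
#' (iii) the tracer bolus co-injected with the neat contrast bolus, its
#' compartment response, physical decay, and frame binning with the default
#' 60 x 3 s + 8 x 15 s scheme starting at injection; (iv) optional additive
#' Gaussian noise on MR signal and duration-scaled multiplicative Gaussian
#' noise on PET frame means, all driven by `config$seed`. Noise-free when
#' both noise parameters are 0.
#'
#' @param config A [phantom_config()].
#' @return A list of class `phantom_dataset` with elements `truth_flow`,
#'   `aif_conc`, `myo_conc` (mmol/L), `aif_activity`, `myo_activity`
#'   (kBq/mL, fine grid, decayed), `mr_signal_aif`, `mr_signal_myo` (a.u.),
#'   `pet_tac_aif`, `pet_tac_myo` (as-measured [framed_tac()]s),
#'   `injection_time` (tracer/neat arrival, s) and `config`.
#' @export
simulate_protocol <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  c_ <- config
  if (!is.null(c_$seed)) set.seed(c_$seed)
  neat_arrival <- c_$dilute_arrival + c_$interbolus_delay
  scheme <- default_frame_scheme(injection_time = neat_arrival)
  t_end <- max(c_$n_dynamics * 60 / c_$heart_rate,
               scheme$start[nrow(scheme)] + scheme$duration[nrow(scheme)]) + 5
  fine_dt <- 0.05
  tg <- seq(0, t_end, by = fine_dt)

  gd_boluses <- rbind(
    bolus_spec(c_$peak_conc / c_$dose_ratio, c_$dilute_arrival, c_$shape_alpha, c_$shape_beta),
    bolus_spec(c_$peak_conc, neat_arrival, c_$shape_alpha, c_$shape_beta)
  )
  aif_conc <- generate_aif(gd_boluses, tg, unit = "mmol/L")
  myo_conc <- simulate_tissue_curve(aif_conc, c_$flow, c_$dispersion_volume, c_$tissue_mass)

  tracer <- bolus_spec(c_$pet_peak_activity, neat_arrival, c_$shape_alpha, c_$shape_beta)
  aif_act <- generate_aif(tracer, tg, unit = "kBq/mL")
  myo_act <- simulate_tissue_curve(aif_act, c_$flow, c_$dispersion_volume, c_$tissue_mass)

  # MR sampling: one dynamic per heartbeat
  ts <- (seq_len(c_$n_dynamics) - 1) * 60 / c_$heart_rate
  samp <- function(curve) approx(curve$time, curve$value, ts)$y
  sig_a <- srflash_signal(samp(aif_conc), c_$mr_protocol)
  sig_m <- srflash_signal(samp(myo_conc), c_$mr_protocol)
  if (c_$noise_mr_sigma > 0) {
    sig_a <- sig_a + rnorm(length(ts), 0, c_$noise_mr_sigma)
    sig_m <- sig_m + rnorm(length(ts), 0, c_$noise_mr_sigma)
  }

  # PET: physical decay from injection, then frame binning
  lam <- log(2) / (c_$half_life * 60)
  dec <- ifelse(tg >= neat_arrival, exp(-lam * (tg - neat_arrival)), 1)
  decayed <- function(curve) sampled_curve(tg, curve$value * dec, unit = "kBq/mL")
  tac_a <- bin_frames(decayed(aif_act), scheme, reference_time = neat_arrival)
  tac_m <- bin_frames(decayed(myo_act), scheme, reference_time = neat_arrival)
  if (c_$noise_pet_cv > 0) {
    jig <- function(tac) {
      cv <- c_$noise_pet_cv / sqrt(tac$duration)
      framed_tac(tac_scheme(tac),
                 tac$activity * (1 + rnorm(nrow(tac), 0, cv)),
                 decay_corrected = FALSE, reference_time = neat_arrival)
    }
    tac_a <- jig(tac_a)
    tac_m <- jig(tac_m)
  }

  structure(list(
    truth_flow = c_$flow,
    aif_conc = aif_conc, myo_conc = myo_conc,
    aif_activity = decayed(aif_act), myo_activity = decayed(myo_act),
    mr_signal_aif = sampled_curve(ts, sig_a, unit = "a.u."),
    mr_signal_myo = sampled_curve(ts, sig_m, unit = "a.u."),
    pet_tac_aif = tac_a, pet_tac_myo = tac_m,
    injection_time = neat_arrival,
    config = c_
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "# A phantom_dataset: truth flow %.3g mL/g/min\n",
    "#   MR: %d dynamics (dt %.3g s), dilute @%g s, neat @%g s\n",
    "#   PET: %d frames from injection @%g s\n"),
    x$truth_flow, nrow(x$mr_signal_aif),
    x$mr_signal_aif$time[2] - x$mr_signal_aif$time[1],
    x$config$dilute_arrival, x$injection_time,
    nrow(x$pet_tac_aif), x$injection_time))
  invisible(x)
}
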