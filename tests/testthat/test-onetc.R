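test_that("frame schemes validate contiguity and the default spans 300 s", {
  sch <- default_frame_scheme()
  expect_equal(nrow(sch), 68)
  expect_equal(sch$duration, c(rep(3, 60), rep(15, 8)))
  expect_equal(tail(sch$start + sch$duration, 1), 300)
  expect_equal(sch$start[-1], head(sch$start + sch$duration, -1))
  expect_error(frame_scheme(c(0, 5), c(3, 3)), "contiguous")
  expect_error(frame_scheme(0, 0), "positive")
})

test_that("bin_frames: constants exact, linear ramps hit frame midpoints", {
  tg <- seq(0, 310, by = 0.5)
  sch <- default_frame_scheme()
  const <- bin_frames(sampled_curve(tg, rep(4.2, length(tg)), unit = "kBq/mL"), sch)
  expect_equal(const$activity, rep(4.2, 68), tolerance = 1e-12)

  ramp <- bin_frames(sampled_curve(tg, 2 * tg + 1, unit = "kBq/mL"), sch)
  expect_equal(ramp$activity, 2 * (sch$start + sch$duration / 2) + 1,
               tolerance = 1e-9)

  short <- sampled_curve(seq(0, 100, 0.5), rep(1, 201), unit = "kBq/mL")
  expect_error(bin_frames(short, sch), "cover")
})

test_that("decay correction: exact round trip, infinite half-life, state flag", {
  sch <- default_frame_scheme()
  lam <- log(2) / (9.96 * 60)
  tg <- seq(0, 310, by = 0.01)   # fine enough that binning error < 1e-11
  A0 <- 7.5
  measured <- bin_frames(sampled_curve(tg, A0 * exp(-lam * tg), unit = "kBq/mL"), sch)
  corrected <- decay_correct(measured)     # default half-life is the 13N value
  expect_lt(max(abs(corrected$activity - A0)) / A0, 1e-10)
  expect_true(is_decay_corrected(corrected))
  expect_error(decay_correct(corrected), "already decay-corrected")

  near_stable <- decay_correct(measured, half_life = 1e12)
  expect_equal(near_stable$activity, measured$activity, tolerance = 1e-9)
  expect_error(decay_correct(measured, half_life = -1), "positive")
})

test_that("1TC fit recovers known parameters from model-generated TACs", {
  # independent generation: cumulative-trapezoid evaluation of the
  # convolution integral, not the package's recursive kernel
  K1 <- 1.0 / 60; k2 <- 0.2 / 60; vb <- 0.1     # s^-1 units
  tg <- seq(0, 310, by = 0.05)
  ca <- 100 * perfquant:::gamma_variate(tg, 5, 3, 4)
  grow <- ca * exp(k2 * tg)
  cum <- c(0, cumsum(diff(tg) * (head(grow, -1) + tail(grow, -1)) / 2))
  conv <- exp(-k2 * tg) * cum
  ct <- (1 - vb) * K1 * conv + vb * ca

  sch <- default_frame_scheme()
  aif_tac <- bin_frames(sampled_curve(tg, ca, unit = "kBq/mL"), sch,
                        decay_corrected = TRUE)
  tis_tac <- bin_frames(sampled_curve(tg, ct, unit = "kBq/mL"), sch,
                        decay_corrected = TRUE)
  fit <- fit_1tc(aif_tac, tis_tac, fit_vb = TRUE)
  expect_true(fit$converged)
  expect_equal(fit$params$K1, 1.0, tolerance = 0.02)
  expect_equal(fit$params$k2, 0.2, tolerance = 0.02)
  expect_equal(fit$params$vb, 0.1, tolerance = 0.02)
  expect_equal(fit$mbf, fit$params$K1)
})

test_that("1TC guards: zero tissue, window bounds, decay state, scheme match", {
  sch <- default_frame_scheme()
  aif <- framed_tac(sch, seq_len(68), decay_corrected = TRUE)
  zero <- framed_tac(sch, rep(0, 68), decay_corrected = TRUE)
  fit <- fit_1tc(aif, zero)
  expect_identical(fit$params$K1, 0)
  expect_true(fit$converged)

  raw <- framed_tac(sch, seq_len(68), decay_corrected = FALSE)
  expect_error(fit_1tc(raw, zero), "decay-corrected")
  expect_error(fit_1tc(aif, zero, window = 400), "exceeds")
  other <- framed_tac(default_frame_scheme(injection_time = 5), seq_len(68),
                      decay_corrected = TRUE)
  expect_error(fit_1tc(aif, other), "same frame scheme")
})

test_that("phantom PET arm: frame binning changes MBF by < 3%, k2 tracks washout", {
  ds <- simulate_protocol(noise_free_config(3))
  binned <- quantify_pet_phantom(ds)

  # same underlying curves on a fine 1-s frame grid
  fine_sch <- frame_scheme(ds$injection_time + 0:299, rep(1, 300))
  cal <- ds$config$dispersion_volume / ds$config$tissue_mass
  fine_fit <- fit_1tc(
    decay_correct(bin_frames(ds$aif_activity, fine_sch,
                             reference_time = ds$injection_time)),
    decay_correct(bin_frames(ds$myo_activity, fine_sch,
                             reference_time = ds$injection_time)),
    calibration = cal)
  expect_lt(abs(binned$mbf - fine_fit$mbf) / fine_fit$mbf, 0.03)

  # no tracer trapping: fitted k2 positive, consistent with Q/V_d
  kw <- 3 * ds$config$tissue_mass / ds$config$dispersion_volume  # min^-1
  expect_gt(binned$params$k2, 0)
  expect_equal(binned$params$k2, kw, tolerance = 0.10)
})

test_that("window sensitivity is reported when diagnostics are on", {
  ds <- simulate_protocol(noise_free_config(2))
  fit <- quantify_pet_phantom(ds, diagnostics = TRUE)
  expect_equal(fit$window_sweep$window, c(180, 240, 300))
  expect_true(all(is.finite(fit$window_sweep$mbf)))
  # noise-free: the window hardly matters
  expect_lt(diff(range(fit$window_sweep$mbf)) / fit$mbf, 0.05)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(glance(fit)$fit_window, 240)
})
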