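test_that("SR-FLASH forward model: baseline, ceiling, monotonicity, saturation", {
  p <- mr_protocol()  # TI 100 ms, flip 10, T10 3000, r1 5, M0 1000
  s0 <- p$m0 * sin(p$flip_deg * pi / 180) * (1 - exp(-p$ti_ms / p$t10_ms))
  expect_equal(srflash_signal(0, p), s0, tolerance = 1e-12)
  expect_gt(s0, 0)

  # saturation ceiling M0 sin(alpha)
  expect_equal(srflash_signal(1e6, p), p$m0 * sin(p$flip_deg * pi / 180),
               tolerance = 1e-6)

  grid <- seq(0, 12, by = 0.01)
  expect_true(all(diff(srflash_signal(grid, p)) > 0))

  # visible sub-linearity: tenfold concentration gives less than tenfold signal
  p2 <- mr_protocol(ti_ms = 100, flip_deg = 10, t10_ms = 2000, r1_relaxivity = 5)
  expect_lt(srflash_signal(4, p2) / srflash_signal(0.4, p2), 10)

  expect_error(srflash_signal(-0.1, p), "non-negative")
})

test_that("LUT tabulates the forward model and inverts it", {
  p <- mr_protocol()
  lut2 <- build_lut(p, conc_max = 5, n_points = 2)
  expect_equal(lut2$conc, c(0, 5))
  expect_equal(lut2$signal[1], srflash_signal(0, p))

  lut <- build_lut(p, conc_max = 6, n_points = 4096)
  set.seed(11)
  conc <- sort(runif(50, 0, 5.5))
  curve <- sampled_curve(seq_along(conc), srflash_signal(conc, p), unit = "a.u.")
  back <- signal_to_concentration(curve, lut, baseline_signal = srflash_signal(0, p))
  expect_lt(max(abs(back$value - conc)), 1e-3)
})

test_that("signal_to_concentration calibrates, clamps, and flags saturation", {
  p <- mr_protocol()
  lut <- build_lut(p, conc_max = 5, n_points = 2048)

  # proportional M0 miscalibration is absorbed by the baseline rescale
  scale <- 1.7
  conc <- c(0, 0.05, 0.2, 0.4, 0.1)
  curve <- sampled_curve(1:5, scale * srflash_signal(conc, p), unit = "a.u.")
  back <- signal_to_concentration(curve, lut, scale * srflash_signal(0, p))
  expect_equal(back$value, conc, tolerance = 1e-3)

  base <- srflash_signal(0, p)
  flat <- sampled_curve(1:4, rep(base, 4), unit = "a.u.")
  expect_equal(signal_to_concentration(flat, lut, base)$value, rep(0, 4))

  dip <- sampled_curve(1:4, base * c(1, 0.99, 1.01, 0.99), unit = "a.u.")
  out <- signal_to_concentration(dip, lut, base)
  expect_equal(attr(out, "n_clamped"), 2)
  expect_true(all(out$value >= 0))

  hot <- sampled_curve(1:3, c(base, base, srflash_signal(1e5, p) * 1.01),
                       unit = "a.u.")
  expect_error(signal_to_concentration(hot, lut, base), "t = 3")
})

test_that("baseline correction subtracts the pre-contrast mean and is idempotent", {
  cur <- sampled_curve(1:10, c(rep(10, 8), 30, 50), unit = "a.u.")
  bc <- baseline_correct(cur, 8)
  expect_equal(bc$value, c(rep(0, 8), 20, 40))
  expect_equal(baseline_correct(bc, 8)$value, bc$value)
  expect_equal(baseline_correct(sampled_curve(1:5, rep(7, 5)), 3)$value, rep(0, 5))
  expect_error(baseline_correct(cur, 10), "n_baseline")
})

test_that("dual-bolus assembly scales by dose ratio and aligns the foot", {
  dil <- test_aif(dt = 1, t_end = 120, peak = 0.05, arrival = 10)
  foot <- dil$time[which(dil$value > 0.05 * max(dil$value))[1]]

  ident <- assemble_dual_bolus_aif(dil, dose_ratio = 1, neat_arrival = foot)
  expect_equal(ident$value, dil$value, tolerance = 1e-12)

  x10 <- assemble_dual_bolus_aif(dil, dose_ratio = 10, neat_arrival = foot)
  expect_equal(max(x10$value), 10 * max(dil$value), tolerance = 1e-12)

  # known-shift recovery onto a longer clock
  dil_long <- generate_aif(bolus_spec(0.05, 10), seq(0, 240, by = 1))
  shifted <- assemble_dual_bolus_aif(dil_long, 10, neat_arrival = 137)
  foot_new <- shifted$time[which(shifted$value > 0.05 * max(shifted$value))[1]]
  expect_lte(abs(foot_new - 137), 1)

  # equivariance under time translation of the input
  trans <- sampled_curve(dil_long$time, c(rep(0, 7), head(dil_long$value, -7)),
                         unit = "mmol/L")
  s1 <- assemble_dual_bolus_aif(dil_long, 10, neat_arrival = 150)
  s2 <- assemble_dual_bolus_aif(trans, 10, neat_arrival = 150)
  expect_equal(s1$value, s2$value, tolerance = 1e-9)

  flat <- sampled_curve(0:20, rep(0, 21), unit = "mmol/L")
  expect_error(assemble_dual_bolus_aif(flat, 10, neat_arrival = 5), "foot")
})

test_that("AIF integral normalization matches integrals and is idempotent", {
  aif <- boxcar_curve(height = 2, width = 10, dt = 0.1, t_end = 40)
  myo <- boxcar_curve(height = 1, width = 10, dt = 0.1, t_end = 40)
  out <- normalize_aif_integral(aif, myo)
  expect_equal(max(out$value), 1, tolerance = 1e-12)          # hand integration
  expect_equal(curve_integral(out), curve_integral(myo), tolerance = 1e-12)

  # invariant to any positive prior scaling of the AIF
  for (c_ in c(0.25, 4)) {
    scaled <- sampled_curve(aif$time, c_ * aif$value, unit = "mmol/L")
    expect_equal(normalize_aif_integral(scaled, myo)$value, out$value,
                 tolerance = 1e-12)
  }
  # idempotent; identity when integrals already match
  expect_equal(normalize_aif_integral(out, myo)$value, out$value,
               tolerance = 1e-12)
  zero <- sampled_curve(aif$time, rep(0, nrow(aif)), unit = "mmol/L")
  expect_error(normalize_aif_integral(zero, myo), "zero time-integral")
})

test_that("gamma-variate fit recovers an exact bolus and denoises a noisy one", {
  tg <- seq(0, 120, by = 1)
  truth <- 0.05 * perfquant:::gamma_variate(tg, 12, 3, 4)
  fit <- fit_gamma_variate(sampled_curve(tg, truth, unit = "a.u."))
  expect_true(fit$converged)
  expect_equal(fit$params$peak, 0.05, tolerance = 1e-4)
  expect_equal(fit$params$arrival, 12, tolerance = 1e-3)

  set.seed(5)
  noisy <- truth + rnorm(length(tg), 0, 0.002)
  fit <- fit_gamma_variate(sampled_curve(tg, noisy, unit = "a.u."))
  expect_lt(max(abs(fit$fitted$value - truth)), 0.004)
})
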