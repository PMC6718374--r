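test_that("fermi_response: branches agree, delay gates onset, k=0 plateau", {
  t <- seq(0, 60, by = 0.5)
  # continuity across the tau0 sign change
  a <- fermi_response(t, 1, 0.2, 1e-9)
  b <- fermi_response(t, 1, 0.2, -1e-9)
  expect_equal(a, b, tolerance = 1e-6)

  # amplitude parameter equals the response at onset
  for (tau0 in c(-40, -5, 0, 5, 40)) {
    r <- fermi_response(c(3, 10, 20), 2.5, 0.1, tau0, delay_taud = 3)
    expect_equal(r[1], 2.5, tolerance = 1e-12)
  }
  expect_equal(fermi_response(c(0, 1.9), 1, 0.1, 5, delay_taud = 2), c(0, 0))

  # strongly negative tau0 degenerates to a pure exponential
  r <- fermi_response(t, 1.5, 0.1, -300)
  expect_equal(r, 1.5 * exp(-0.1 * t), tolerance = 1e-8)
  # no overflow on extreme parameters
  expect_true(all(is.finite(fermi_response(t, 1, 5, -600))))
  expect_true(all(is.finite(fermi_response(t, 1, 5, 300))))
})

test_that("convolve_aif equals the brute-force direct-sum oracle", {
  set.seed(3)
  for (rep in 1:4) {
    n <- sample(40:80, 1)
    dt <- sample(c(0.5, 1, 2), 1)
    aif <- sampled_curve((0:(n - 1)) * dt, abs(rnorm(n)), unit = "mmol/L")
    p <- list(amplitude = runif(1, 0.01, 0.5), decay_k = runif(1, 0.01, 0.5),
              width_tau0 = runif(1, -30, 30), delay_taud = sample(0:3, 1) * dt)
    got <- convolve_aif(aif, p)$value
    r <- fermi_response(aif$time - aif$time[1], p$amplitude, p$decay_k,
                        p$width_tau0, p$delay_taud)
    want <- direct_conv(aif$value, r, dt)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
})

test_that("convolution limits: zero amplitude; narrow unit-area response", {
  aif <- test_aif(dt = 0.5)
  z <- convolve_aif(aif, list(amplitude = 0, decay_k = 0.1, width_tau0 = 5,
                              delay_taud = 0))
  expect_true(all(z$value == 0))

  # near-delta response with unit area reproduces the AIF (delayed by the
  # kernel centroid)
  k <- 20; tau0 <- 0.2
  area <- integrate(function(t) fermi_response(t, 1, k, tau0), 0, 50)$value
  centroid <- integrate(function(t) t * fermi_response(t, 1, k, tau0), 0, 50)$value / area
  sp <- convolve_aif(aif, list(amplitude = 1 / area, decay_k = k,
                               width_tau0 = tau0, delay_taud = 0), upsample = 8)
  inner <- aif$time > 15 & aif$time < 100
  want <- approx(aif$time + centroid, aif$value, aif$time[inner])$y
  expect_lt(max(abs(sp$value[inner] - want)) / max(aif$value), 0.02)
})

test_that("fit_fermi recovers known parameters on both response branches", {
  aif <- test_aif(dt = 1, t_end = 150)
  for (p in list(list(amplitude = 0.05, decay_k = 0.08, width_tau0 = 6, delay_taud = 2),
                 list(amplitude = 0.12, decay_k = 0.15, width_tau0 = -25, delay_taud = 0))) {
    tissue <- convolve_aif(aif, p, upsample = 4)
    fit <- fit_fermi(aif, tissue)
    expect_true(fit$converged)
    expect_equal(fit$params$amplitude, p$amplitude, tolerance = 0.01)
    expect_equal(fit$mbf, p$amplitude * 60, tolerance = 0.01)
  }
})

test_that("fit_fermi: zero tissue gives zero MBF; degenerate AIF errors", {
  aif <- test_aif(dt = 1)
  zero <- sampled_curve(aif$time, rep(0, nrow(aif)), unit = "mmol/L")
  fit <- fit_fermi(aif, zero)
  expect_true(fit$converged)
  expect_identical(fit$mbf, 0)
  expect_error(fit_fermi(zero, zero), "degenerate AIF")
  expect_error(fit_fermi(aif, zero[1:50, ]), "time grid")
})

test_that("fitted MBF scales with the tissue curve and inversely with the AIF", {
  aif <- test_aif(dt = 1, t_end = 150)
  tissue <- convolve_aif(aif, list(amplitude = 0.08, decay_k = 0.1,
                                   width_tau0 = 4, delay_taud = 0), upsample = 4)
  base <- fit_fermi(aif, tissue)$mbf
  for (c_ in c(0.5, 2)) {
    t2 <- sampled_curve(tissue$time, c_ * tissue$value, unit = "mmol/L")
    expect_equal(fit_fermi(aif, t2)$mbf, c_ * base, tolerance = 1e-3)
    a2 <- sampled_curve(aif$time, c_ * aif$value, unit = "mmol/L")
    expect_equal(fit_fermi(a2, tissue)$mbf, base / c_, tolerance = 1e-3)
  }
})

test_that("tidy/glance/autoplot methods work on fermi fits", {
  aif <- test_aif(dt = 1)
  tissue <- convolve_aif(aif, list(amplitude = 0.05, decay_k = 0.1,
                                   width_tau0 = 5, delay_taud = 0))
  fit <- fit_fermi(aif, tissue)
  td <- tidy(fit)
  expect_setequal(td$term, c("amplitude", "decay_k", "width_tau0", "delay_taud"))
  expect_equal(glance(fit)$mbf, fit$mbf)
  expect_s3_class(autoplot(fit), "ggplot")
})
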