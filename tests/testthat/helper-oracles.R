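# Independent oracles and small fixture builders used across tests.

# brute-force O(n^2) trapezoid-weighted causal convolution
direct_conv <- function(a, r, dt) {
  n <- length(a)
  out <- numeric(n)
  for (i in 2:n) {      # integral over a zero-length interval is 0
    s <- 0
    for (j in seq_len(i)) {
      w <- if (j == 1 || j == i) 0.5 else 1
      s <- s + w * a[j] * r[i - j + 1]
    }
    out[i] <- s * dt
  }
  out
}

# ICC(2,1) through R's own two-way ANOVA decomposition (independent of the
# mean-squares arithmetic in the package)
icc21_aov <- function(x, y) {
  d <- data.frame(score = c(x, y),
                  subject = factor(rep(seq_along(x), 2)),
                  rater = factor(rep(1:2, each = length(x))))
  ms <- anova(stats::lm(score ~ subject + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- length(x); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# a smooth single-bolus AIF on a uniform grid, for fit tests
test_aif <- function(dt = 1, t_end = 120, peak = 1, arrival = 10,
                     unit = "mmol/L") {
  tg <- seq(0, t_end, by = dt)
  generate_aif(bolus_spec(peak, arrival), tg, unit = unit)
}

boxcar_curve <- function(height, width, dt = 0.1, t_end = width * 3,
                         unit = "mmol/L") {
  tg <- seq(0, t_end, by = dt)
  sampled_curve(tg, ifelse(tg > 0 & tg <= width, height, 0), unit = unit)
}

noise_free_config <- function(flow, ...) {
  phantom_config(flow = flow, noise_mr_sigma = 0, noise_pet_cv = 0, ...)
}
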