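#' Bland-Altman agreement analysis
#'
#' Bias and 95% limits of agreement of paired measurements. The difference
#' direction is `x - y`; with `x` = CMR and `y` = PET, CMR underestimation
#' yields a negative bias. Limits are `bias +/- 1.96 * sd(x - y)` with the
#' n-1 denominator and no small-sample correction.
#'
#' @param data A data frame of paired measurements; rows with a missing
#'   side are dropped (their count is reported).
#' @param x,y Columns holding the two modalities (tidy-eval; default
#'   `x`, `y`).
#' @return A one-row tibble: `n`, `n_dropped`, `bias`, `loa_low`,
#'   `loa_high`.
#' @examples
#' bland_altman(tibble::tibble(x = c(1, 2, 3), y = c(2, 2, 2)))
#' @export
bland_altman <- function(data, x = x, y = y) {
  p <- paired_xy(data, {{ x }}, {{ y }})
  if (nrow(p) < 2) abort("need at least 2 complete pairs for Bland-Altman analysis.")
  d <- p$x - p$y
  bias <- mean(d)
  s <- sd(d)
  tibble(n = nrow(p), n_dropped = attr(p, "n_dropped"),
         bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC computed
#' from the ANOVA mean squares of the subjects-by-raters table:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n} (MS_C - MS_E)}}
#' with \eqn{k = 2} raters. Unlike Pearson's r it penalizes systematic
#' offsets between the modalities, which is why it is the defensible form
#' both for test-retest repeatability and for cross-modality agreement.
#'
#' @inheritParams bland_altman
#' @return The ICC (a scalar in (-Inf, 1]).
#' @export
icc21 <- function(data, x = x, y = y) {
  p <- paired_xy(data, {{ x }}, {{ y }})
  n <- nrow(p)
  if (n < 2) abort("need at least 2 complete pairs for the ICC.")
  k <- 2
  m <- cbind(p$x, p$y)
  if (var(as.vector(m)) == 0) abort("zero total variance: ICC undefined.")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' Pearson correlation of paired measurements
#'
#' Product-moment correlation with the two-tailed p-value from the t
#' transform on n-2 degrees of freedom (via [stats::cor.test()]).
#'
#' @inheritParams bland_altman
#' @return A one-row tibble: `n`, `r`, `p_value`.
#' @export
pearson_agreement <- function(data, x = x, y = y) {
  p <- paired_xy(data, {{ x }}, {{ y }})
  if (nrow(p) < 3) abort("need at least 3 complete pairs for a Pearson p-value.")
  if (sd(p$x) == 0 || sd(p$y) == 0) abort("zero variance: correlation undefined.")
  ct <- cor.test(p$x, p$y, method = "pearson", alternative = "two.sided")
  tibble(n = nrow(p), r = unname(ct$estimate), p_value = ct$p.value)
}

paired_xy <- function(data, x, y) {
  x <- dplyr::pull(data, {{ x }})
  y <- dplyr::pull(data, {{ y }})
  keep <- is.finite(x) & is.finite(y)
  out <- tibble(x = x[keep], y = y[keep])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Full cross-modality agreement report
#'
#' Pearson r and p, ICC(2,1), and Bland-Altman bias with 95% limits of
#' agreement for paired MBF measurements — the statistical layer used to
#' compare CMR and PET flow estimates.
#'
#' @inheritParams bland_altman
#' @return A one-row tibble of class `agreement_report`: `n`, `pearson_r`,
#'   `pearson_p`, `icc`, `bias`, `loa_low`, `loa_high`, with the paired
#'   data attached as attribute `pairs` (used by [autoplot.agreement_report()]).
#' @export
agreement_report <- function(data, x = x, y = y) {
  p <- paired_xy(data, {{ x }}, {{ y }})
  pe <- pearson_agreement(p)
  ba <- bland_altman(p)
  out <- tibble(n = ba$n, pearson_r = pe$r, pearson_p = pe$p_value,
                icc = icc21(p), bias = ba$bias,
                loa_low = ba$loa_low, loa_high = ba$loa_high)
  structure(out, class = c("agreement_report", class(out)), pairs = p)
}

#' Standard AHA 16-segment coronary territory map
#'
#' Assigns each American Heart Association left-ventricular segment to the
#' territory of a main epicardial artery: LAD (1, 2, 7, 8, 13, 14), RCA
#' (3, 4, 9, 10, 15) and LCX (5, 6, 11, 12, 16).
#'
#' @return A 16-row tibble with columns `segment_id`, `territory`.
#' @export
aha16_territories <- function() {
  tibble(
    segment_id = 1:16,
    territory = c("LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
                  "LAD", "LAD", "RCA", "RCA", "LCX", "LCX",
                  "LAD", "LAD", "RCA", "LCX")
  )
}

#' Aggregate segmental MBF to coronary territories and a global mean
#'
#' Territory MBF is the unweighted mean of its segments; the global value
#' is the unweighted mean over all mapped segments.
#'
#' @param segment_table Data frame with columns `segment_id` (unique, within
#'   the mapping's domain) and `mbf` (mL/g/min).
#' @param mapping A segment-to-territory map like [aha16_territories()];
#'   must be a partition of its segment ids.
#' @return A tibble with columns `territory`, `n_segments`, `mbf`; the
#'   territories in mapping order followed by a `"global"` row.
#' @export
territory_aggregate <- function(segment_table, mapping = aha16_territories()) {
  if (anyDuplicated(segment_table$segment_id)) {
    abort("`segment_table` has duplicated segment ids.")
  }
  if (anyDuplicated(mapping$segment_id)) {
    abort("`mapping` assigns some segment to more than one territory.")
  }
  missing <- setdiff(mapping$segment_id, segment_table$segment_id)
  if (length(missing) > 0) {
    abort(sprintf("segment table is missing segments: %s.",
                  paste(missing, collapse = ", ")))
  }
  joined <- dplyr::inner_join(mapping, segment_table, by = "segment_id")
  per_ter <- joined |>
    dplyr::group_by(.data$territory) |>
    dplyr::summarise(n_segments = dplyr::n(), mbf = mean(.data$mbf),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$territory, unique(mapping$territory)))
  dplyr::bind_rows(per_ter,
                   tibble(territory = "global", n_segments = nrow(joined),
                          mbf = mean(joined$mbf)))
}
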