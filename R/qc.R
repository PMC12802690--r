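#' Leave-one-out Z-score outlier flags for one site
#'
#' For each sample i, computes the Z score of its value against the mean
#' and standard deviation of the remaining samples,
#' Z_i = (x_i - mean_(-i)) / sd_(-i), and flags |Z_i| > `z_thresh`.
#' Flagged values are intended to be set missing before trajectory
#' fitting, so a single aberrant sample cannot masquerade as a nonlinear
#' trajectory. The leave-one-out sd is floored at 1e-6 so identical-value
#' vectors give Z = 0 rather than 0/0.
#'
#' @param values Numeric vector of one site's beta values (>= 5
#'   non-missing).
#' @param z_thresh Threshold on |Z| (default 5 standard deviations).
#' @return Logical vector the length of `values`; `NA` inputs map to
#'   `FALSE`.
#' @export
loo_zscore_outliers <- function(values, z_thresh = 5) {
  ok <- !is.na(values)
  if (sum(ok) < 5) mt_abort("loo_zscore_outliers needs >= 5 non-missing values")
  x <- values[ok]
  n <- length(x)
  s <- sum(x); ss <- sum(x^2)
  m_loo <- (s - x) / (n - 1)
  # leave-one-out variance from running sums
  v_loo <- (ss - x^2 - (n - 1) * m_loo^2) / (n - 2)
  sd_loo <- pmax(sqrt(pmax(v_loo, 0)), 1e-6)
  z <- (x - m_loo) / sd_loo
  out <- rep(FALSE, length(values))
  out[ok] <- abs(z) > z_thresh
  out
}

#' Pre-trajectory site filters
#'
#' `filter_nonvariable()` excludes sites whose middle-80% range (the
#' 10th-to-90th percentile span, linear interpolation) is below
#' `min_range` (default 5% DNA methylation, i.e. 0.05 on the proportion
#' scale; exclusion uses strict `<`). `filter_constant()` excludes sites
#' whose values are all above `hi` or all below `lo` (strict
#' inequalities). `qc_filter()` applies both plus the leave-one-out
#' outlier mask and returns the filtered matrix with a per-site report.
#'
#' @param beta Sites x samples beta matrix.
#' @param middle_fraction Central fraction of values defining the range.
#' @param min_range Minimum middle-range to be considered variable.
#' @return A tibble: `site_id`, `excluded`, `reason`, and the statistic
#'   used (`middle80_range` or none).
#' @export
filter_nonvariable <- function(beta, middle_fraction = 0.8, min_range = 0.05) {
  tail_p <- (1 - middle_fraction) / 2
  rng <- apply(beta, 1, function(x) {
    x <- x[!is.na(x)]
    q <- quantile(x, c(tail_p, 1 - tail_p), names = FALSE, type = 7)
    q[2] - q[1]
  })
  tibble(site_id = rownames(beta),
         middle80_range = unname(rng),
         excluded = rng < min_range,
         reason = ifelse(rng < min_range, "nonvariable", "none"))
}

#' @rdname filter_nonvariable
#' @param hi,lo Bounds defining consistently hyper-/hypo-methylated sites.
#' @export
filter_constant <- function(beta, hi = 0.90, lo = 0.10) {
  all_hi <- apply(beta, 1, function(x) all(x[!is.na(x)] > hi))
  all_lo <- apply(beta, 1, function(x) all(x[!is.na(x)] < lo))
  exc <- unname(all_hi | all_lo)
  tibble(site_id = rownames(beta),
         excluded = exc,
         reason = ifelse(exc, "constant", "none"))
}

#' @rdname filter_nonvariable
#' @param z_thresh Leave-one-out Z threshold passed to
#'   [loo_zscore_outliers()].
#' @return `qc_filter()` returns a list: `beta` (retained sites, outlier
#'   values set `NA`), `report` (per-site tibble with exclusion reason and
#'   outlier count).
#' @export
qc_filter <- function(beta, middle_fraction = 0.8, min_range = 0.05,
                      hi = 0.90, lo = 0.10, z_thresh = 5) {
  validate_beta_matrix(beta)
  masked <- beta
  n_out <- integer(nrow(beta))
  for (i in seq_len(nrow(beta))) {
    fl <- loo_zscore_outliers(beta[i, ], z_thresh = z_thresh)
    n_out[i] <- sum(fl)
    if (n_out[i]) masked[i, fl] <- NA
  }
  nv <- filter_nonvariable(masked, middle_fraction, min_range)
  ct <- filter_constant(masked, hi, lo)
  excluded <- nv$excluded | ct$excluded
  reason <- ifelse(nv$excluded, "nonvariable",
                   ifelse(ct$excluded, "constant", "none"))
  report <- tibble(site_id = rownames(beta),
                   n_outliers = n_out,
                   middle80_range = nv$middle80_range,
                   excluded = excluded, reason = reason)
  list(beta = masked[!excluded, , drop = FALSE], report = report)
}
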