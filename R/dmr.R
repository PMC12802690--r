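#' Candidate differentially methylated regions
#'
#' Chains significant sites (dDMPs) into maximal runs in which every
#' consecutive pair lies within `max_gap` base pairs on the same
#' chromosome, keeping runs with at least `min_dmps` sites. The gap
#' bound applies to consecutive sites, so a chain may span more than
#' `max_gap` in total.
#'
#' @param site_results Tibble from [fit_dmps()] (needs `site_id`, `dmp`).
#' @param annotation Probe annotation (`site_id`, `chrom`, `position`).
#' @param max_gap Maximum distance between consecutive dDMPs (bp).
#' @param min_dmps Minimum dDMPs per candidate.
#' @return Tibble of candidates: `region_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `n_dmps`, `site_ids` (list column).
#' @export
build_candidates <- function(site_results, annotation, max_gap = 500, min_dmps = 3) {
  d <- site_results |>
    filter(.data$dmp) |>
    dplyr::inner_join(annotation |> select("site_id", "chrom", "position"),
                      by = "site_id") |>
    arrange(.data$chrom, .data$position)
  if (!nrow(d)) {
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_dmps = integer(),
                  site_ids = list()))
  }
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 diff(d$position) > max_gap)
  d$run <- cumsum(new_run)
  d |>
    group_by(.data$run) |>
    summarise(chrom = dplyr::first(.data$chrom),
              start = min(.data$position), end = max(.data$position),
              n_dmps = dplyr::n(), site_ids = list(.data$site_id),
              .groups = "drop") |>
    filter(.data$n_dmps >= min_dmps) |>
    mutate(region_id = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)) |>
    select("region_id", "chrom", "start", "end", "n_dmps", "site_ids")
}

#' Inverse-variance region statistic with correlation adjustment
#'
#' Combines per-site effects within a region by fixed-effect
#' inverse-variance meta-analysis generalised to correlated sites: with
#' Sigma = diag(s) R diag(s), the combined effect is
#' B = (1' Sigma^-1 b) / (1' Sigma^-1 1), its standard error
#' (1' Sigma^-1 1)^(-1/2), and p the two-sided normal tail of z = B/se.
#' With R = I this reduces to the classical fixed-effect meta-analysis;
#' with a single site it returns the site's own statistic.
#'
#' @param b Site effects.
#' @param s Site standard errors (> 0).
#' @param R Residual correlation matrix (defaults to identity); a ridge
#'   of 1e-6 is added to the diagonal of Sigma before inversion.
#' @return One-row tibble: `combined_effect`, `combined_se`, `z`, `p`,
#'   `log10_p`.
#' @export
region_statistic <- function(b, s, R = NULL) {
  m <- length(b)
  if (length(s) != m) mt_abort("b and s must have equal length")
  if (any(s <= 0)) mt_abort("standard errors must be > 0")
  if (is.null(R)) R <- diag(m)
  Sigma <- diag(s, m) %*% R %*% diag(s, m)
  # ridge only when needed so the R = I case stays exactly the classical
  # fixed-effect meta-analysis
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(Sigma + diag(1e-6 * diag(Sigma), m)),
                   error = function(e)
                     mt_abort("region covariance is not positive definite after ridge"))
  }
  Sinv1 <- backsolve(ch, forwardsolve(t(ch), rep(1, m)))
  denom <- sum(Sinv1)
  B <- sum(Sinv1 * b) / denom
  se <- 1 / sqrt(denom)
  z <- B / se
  lp <- (log(2) + pnorm(-abs(z), log.p = TRUE)) / log(10)
  tibble(combined_effect = B, combined_se = se, z = z, p = 10^lp, log10_p = lp)
}

#' Call differentially methylated regions
#'
#' Builds candidate regions from dDMPs ([build_candidates()]), estimates
#' each region's residual correlation matrix from methylation residuals
#' after covariate adjustment, computes the correlation-adjusted
#' inverse-variance statistic ([region_statistic()]), Bonferroni-adjusts
#' over the number of candidates, and reports regions with adjusted
#' p < `alpha_region`. Regions mixing effect signs are kept (direction
#' consistency is not required) and flagged via `mixed_direction`.
#'
#' @param site_results Site-level results from [fit_dmps()].
#' @param beta Beta matrix used to estimate residual correlations.
#' @param sheet Sample sheet (for the covariate design).
#' @param annotation Probe annotation with positions and gene symbols.
#' @param covariates Covariates of the site model (for residualisation).
#' @param max_gap,min_dmps Candidate construction parameters.
#' @param alpha_region Threshold on the Bonferroni-adjusted p.
#' @return Tibble of all candidates with `combined_effect`,
#'   `combined_se`, `z`, `p`, `p_adjusted`, `significant`,
#'   `mixed_direction`, `genes`, sorted by p.
#' @export
call_dmrs <- function(site_results, beta, sheet, annotation,
                      covariates = c("sex", "batch"),
                      max_gap = 500, min_dmps = 3, alpha_region = 0.05) {
  cand <- build_candidates(site_results, annotation, max_gap, min_dmps)
  if (!nrow(cand)) return(mutate(cand, combined_effect = numeric(0),
                                 combined_se = numeric(0), z = numeric(0),
                                 p = numeric(0), p_adjusted = numeric(0),
                                 significant = logical(0),
                                 mixed_direction = logical(0),
                                 genes = character(0)))
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  X <- build_design(sheet, c("age_value", covariates))
  H <- X %*% chol2inv(chol(crossprod(X))) %*% t(X)
  stats <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ids <- cand$site_ids[[i]]
    res_i <- site_results[match(ids, site_results$site_id), ]
    Y <- beta[ids, , drop = FALSE]
    ok <- !apply(Y, 2, anyNA)
    resid <- Y[, ok, drop = FALSE] -
      Y[, ok, drop = FALSE] %*% H[ok, ok, drop = FALSE]
    R <- cor(t(resid))
    st <- region_statistic(res_i$effect, res_i$se, R)
    st$mixed_direction <- length(unique(sign(res_i$effect))) > 1
    stats[[i]] <- st
  }
  out <- dplyr::bind_cols(cand, bind_rows(stats))
  out$p_adjusted <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adjusted < alpha_region
  out$genes <- vapply(out$site_ids, function(ids) {
    g <- annotation$gene_symbols[match(ids, annotation$site_id)]
    g <- unique(unlist(strsplit(g[!is.na(g)], ";", fixed = TRUE)))
    paste(sort(g[nzchar(g)]), collapse = ";")
  }, "")
  arrange(out, .data$p)
}
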