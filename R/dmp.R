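#' Per-site linear models of methylation against developmental age
#'
#' Fits, at every site, an ordinary least-squares regression of
#' methylation (proportion scale) on age, controlling for sex and
#' experimental batch, and flags developmentally differentially
#' methylated positions (dDMPs) at the experiment-wide array threshold
#' p < 9e-8. Effects are reported in percentage points of DNA
#' methylation per unit age (per week for pcw ages). Missing values are
#' handled per site by complete-case exclusion; when no values are
#' missing, all sites share one design matrix and the fit is fully
#' vectorised.
#'
#' Extreme p-values are carried in log10 space (`log10_p`); the `p`
#' column underflows to 0 below ~1e-308 and `log10_p` remains exact.
#'
#' @param beta Sites x samples beta matrix.
#' @param sheet Sample sheet (see [read_sample_sheet()]); samples are
#'   matched to `colnames(beta)` by `sample_id`.
#' @param covariates Character vector of sheet columns to adjust for
#'   (categorical columns are expanded to indicator contrasts).
#' @param alpha dDMP significance threshold (default 9e-8).
#' @param min_n Minimum complete cases per site (default 10).
#' @return A tibble with one row per site: `site_id`, `effect` (pp/week),
#'   `se`, `t`, `p`, `log10_p`, `df`, `direction` (`hyper` iff effect >
#'   0), `n_used`, `dmp`.
#' @export
#' @examples
#' sim <- simulate_dataset(n_sites = 20, n_samples = 30, seed = 2)
#' res <- fit_dmps(sim$beta, sim$sheet)
#' head(res)
fit_dmps <- function(beta, sheet, covariates = c("sex", "batch"),
                     alpha = 9e-8, min_n = 10) {
  validate_beta_matrix(beta)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  if (anyNA(sheet$sample_id)) mt_abort("beta contains samples absent from the sheet")
  X <- build_design(sheet, c("age_value", covariates))
  check_full_rank(X)
  res <- ols_scan(beta, X, term = "age_value", min_n = min_n)
  res$effect <- res$effect * 100
  res$se <- res$se * 100
  res |>
    mutate(direction = ifelse(.data$effect > 0, "hyper", "hypo"),
           dmp = .data$log10_p < log10(alpha))
}

# Design matrix with intercept; factors expanded to treatment contrasts.
build_design <- function(sheet, terms) {
  df <- as.data.frame(sheet[, terms, drop = FALSE])
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  stats::model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))), df)
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    mt_abort("design matrix is rank deficient; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  invisible(X)
}

# Vectorised OLS across sites sharing one design; falls back to per-site
# complete-case fits where values are missing. Returns the named term's
# coefficient on the input scale.
ols_scan <- function(Y, X, term, min_n = 10) {
  j <- match(term, colnames(X))
  if (is.na(j)) mt_abort("term '%s' not in design", term)
  n <- ncol(Y); p <- ncol(X)
  full <- !apply(Y, 1, anyNA)
  effect <- se <- tval <- log10p <- rep(NA_real_, nrow(Y))
  dfree <- n_used <- rep(NA_integer_, nrow(Y))
  if (any(full)) {
    H <- chol2inv(chol(crossprod(X)))
    B <- Y[full, , drop = FALSE] %*% X %*% H
    fitted <- B %*% t(X)
    rss <- rowSums((Y[full, , drop = FALSE] - fitted)^2)
    s2 <- rss / (n - p)
    effect[full] <- B[, j]
    se[full] <- sqrt(s2 * H[j, j])
    dfree[full] <- n - p
    n_used[full] <- n
  }
  for (i in which(!full)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) < min_n) next
    Xi <- X[ok, , drop = FALSE]
    qX <- qr(Xi)
    if (qX$rank < p) next
    Hi <- chol2inv(chol(crossprod(Xi)))
    b <- drop(Hi %*% crossprod(Xi, Y[i, ok]))
    rss <- sum((Y[i, ok] - drop(Xi %*% b))^2)
    s2 <- rss / (sum(ok) - p)
    effect[i] <- b[j]
    se[i] <- sqrt(s2 * Hi[j, j])
    dfree[i] <- sum(ok) - p
    n_used[i] <- sum(ok)
  }
  tval <- effect / se
  log10p <- (log(2) + pt(-abs(tval), dfree, log.p = TRUE)) / log(10)
  tibble(site_id = rownames(Y), effect = effect, se = se, t = tval,
         p = 10^log10p, log10_p = log10p, df = dfree, n_used = n_used)
}

#' One-tailed exact binomial direction test
#'
#' Tests whether significant sites are skewed towards one direction of
#' effect. `binom_tail()` is the exact upper/lower tail computed in log
#' space, so p-values far below double underflow remain usable through
#' `log10_p`. `direction_binomial()` counts successes among effects and
#' applies the tail test in the direction of departure from `p0`.
#'
#' @param effects Numeric vector of (significant) site effects.
#' @param success Which direction counts as success: `"hypo"` (effect <
#'   0) or `"hyper"`.
#' @param p0 Null success probability. 0.5 for the genome-wide test; for
#'   per-feature tests use the genome-wide success proportion.
#' @return A one-row tibble: `n_total`, `n_success`, `percent`, `p0`,
#'   `p_one_tailed`, `log10_p`, `alternative`.
#' @export
#' @examples
#' direction_binomial(c(-1, -2, -1.5, 1), success = "hypo")
direction_binomial <- function(effects, success = c("hypo", "hyper"), p0 = 0.5) {
  success <- match.arg(success)
  if (!length(effects)) mt_abort("direction_binomial needs at least one effect")
  if (p0 <= 0 || p0 >= 1) mt_abort("p0 must lie in (0,1)")
  n <- length(effects)
  k <- if (success == "hypo") sum(effects < 0) else sum(effects > 0)
  alt <- if (k / n >= p0) "greater" else "less"
  lp <- binom_tail(k, n, p0, alternative = alt)
  tibble(n_total = n, n_success = k, percent = 100 * k / n, p0 = p0,
         alternative = alt, p_one_tailed = exp(lp), log10_p = lp / log(10))
}

#' @rdname direction_binomial
#' @param k,n Successes and trials.
#' @param alternative `"greater"` for P(X >= k), `"less"` for P(X <= k).
#' @return `binom_tail()` returns the natural-log tail probability.
#' @export
binom_tail <- function(k, n, p0, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (alternative == "greater") {
    if (k == 0) return(0)  # log(1)
    pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  } else {
    pbinom(k, n, p0, lower.tail = TRUE, log.p = TRUE)
  }
}

#' Compare effect magnitudes between hyper- and hypomethylated sites
#'
#' Welch two-sample t-test on absolute effect sizes, with signed group
#' means reported alongside.
#'
#' @param effects_hyper,effects_hypo Effect vectors (pp/week) for the
#'   two direction groups; both must be non-empty.
#' @return One-row tibble: signed and absolute group means, Welch `t`,
#'   `df`, `p`, `log10_p`.
#' @export
compare_effect_magnitude <- function(effects_hyper, effects_hypo) {
  if (!length(effects_hyper) || !length(effects_hypo))
    mt_abort("both direction groups must be non-empty")
  a <- abs(effects_hyper); b <- abs(effects_hypo)
  if (length(a) < 2 || length(b) < 2) mt_abort("need >= 2 effects per group")
  tt <- welch_t(a, b)
  tibble(mean_hyper = mean(effects_hyper), mean_hypo = mean(effects_hypo),
         mean_abs_hyper = mean(a), mean_abs_hypo = mean(b),
         t = tt$t, df = tt$df, p = 10^tt$log10_p, log10_p = tt$log10_p)
}

# Welch t with log-space p (t.test loses extreme tails).
welch_t <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df,
       log10_p = (log(2) + pt(-abs(t), df, log.p = TRUE)) / log(10))
}

#' Global methylation trend across development
#'
#' Averages methylation over (autosomal) sites within each sample and
#' fits the same age + covariates linear model used per site, giving the
#' genome-wide drift in percentage points per week.
#'
#' @param beta Sites x samples beta matrix.
#' @param sheet Sample sheet.
#' @param site_mask Logical or character selector of sites to average
#'   (e.g. autosomal sites); default all.
#' @param covariates Adjustment covariates.
#' @return One-row tibble: `effect` (pp/week), `se`, `t`, `p`, `df`.
#' @export
global_trend <- function(beta, sheet, site_mask = NULL,
                         covariates = c("sex", "batch")) {
  validate_beta_matrix(beta)
  if (!is.null(site_mask)) beta <- beta[site_mask, , drop = FALSE]
  gm <- matrix(colMeans(beta, na.rm = TRUE), nrow = 1,
               dimnames = list("global", colnames(beta)))
  res <- fit_dmps(gm, sheet, covariates = covariates, min_n = 3)
  res |> select("effect", "se", "t", "p", "log10_p", "df")
}

#' Age-by-cell-fraction interaction model
#'
#' Tests, per site, whether the developmental change in methylation
#' differs between two cell fractions (e.g. SATB2+ vs SATB2- nuclei)
#' with a fixed-effects model
#' `beta ~ age * fraction + sex + batch`; the interaction p comes from
#' the age x fraction coefficient. Stratified per-fraction slopes are
#' re-estimated from separate fits on the same samples.
#'
#' @param beta Sites x samples beta matrix.
#' @param sheet Sample sheet with a two-level `fraction` column; each
#'   fraction needs >= 3 samples.
#' @param covariates Additional adjustment covariates.
#' @param alpha Interaction significance threshold.
#' @return Tibble per site: `interaction_effect` (pp/week difference in
#'   slope), `interaction_se`, `interaction_p`, `log10_p`, `significant`,
#'   and per-fraction `effect_<level>` / `p_<level>` columns.
#' @export
fit_interaction <- function(beta, sheet, covariates = c("sex", "batch"),
                            alpha = 9e-8) {
  validate_beta_matrix(beta)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  lev <- sort(unique(sheet$fraction))
  if (length(lev) != 2) mt_abort("fit_interaction needs exactly 2 fraction levels")
  tab <- table(sheet$fraction)
  if (any(tab < 3)) mt_abort("fraction '%s' has fewer than 3 samples",
                             names(tab)[which(tab < 3)[1]])
  df <- as.data.frame(sheet)
  df$fraction <- factor(df$fraction, levels = lev)
  for (v in covariates) if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  fml <- as.formula(paste("~ age_value * fraction",
                          if (length(covariates)) paste("+", paste(covariates, collapse = "+")) else ""))
  X <- stats::model.matrix(fml, df)
  check_full_rank(X)
  int_term <- grep("^age_value:fraction", colnames(X), value = TRUE)
  res <- ols_scan(beta, X, term = int_term, min_n = 6)
  out <- tibble(site_id = res$site_id,
                interaction_effect = res$effect * 100,
                interaction_se = res$se * 100,
                interaction_t = res$t,
                interaction_p = res$p,
                log10_p = res$log10_p,
                significant = res$log10_p < log10(alpha))
  # stratified slopes on the same samples
  for (l in lev) {
    idx <- sheet$fraction == l
    strat <- fit_dmps(beta[, idx, drop = FALSE], sheet[idx, ],
                      covariates = intersect(covariates, names(sheet)),
                      alpha = alpha, min_n = 3)
    out[[paste0("effect_", l)]] <- strat$effect[match(out$site_id, strat$site_id)]
    out[[paste0("p_", l)]] <- strat$p[match(out$site_id, strat$site_id)]
  }
  out
}

#' Mixed-effects cell-type association scan
#'
#' Per site, fits a linear mixed model of methylation on a cell-type
#' term plus fixed covariates with a random donor intercept (fitted by
#' REML for estimates), and tests the cell-type term by likelihood-ratio
#' comparison of nested maximum-likelihood refits. Donors contributing
#' multiple sorted fractions make the random intercept necessary; when
#' the fitted donor variance is singular (zero), the site falls back to
#' a fixed-effects OLS fit and is flagged.
#'
#' @param beta Sites x samples beta matrix.
#' @param sheet Sample sheet with the `term` column and `donor_id`.
#' @param term Sheet column whose association is tested (default
#'   `fraction`).
#' @param covariates Fixed-effect adjustment covariates.
#' @param alpha Significance threshold for the LRT p.
#' @return Tibble per site: `effect` (pp difference for the term's
#'   second level), `se`, `p_lrt`, `log10_p`, `df_lrt`, `significant`,
#'   `singular_fallback`.
#' @export
fit_site_mixed <- function(beta, sheet, term = "fraction",
                           covariates = c("age_value", "sex", "batch"),
                           alpha = 9e-8) {
  validate_beta_matrix(beta)
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(colnames(beta), sheet$sample_id), ]
  df0 <- as.data.frame(sheet)
  for (v in c(term, covariates)) if (is.character(df0[[v]])) df0[[v]] <- factor(df0[[v]])
  rhs <- paste(c(covariates, term), collapse = " + ")
  rhs0 <- paste(covariates, collapse = " + ")
  out <- vector("list", nrow(beta))
  for (i in seq_len(nrow(beta))) {
    df0$y <- beta[i, ]
    d <- df0[!is.na(df0$y), , drop = FALSE]
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(as.formula(paste("y ~", rhs, "+ (1|donor_id)")),
                 data = d, REML = TRUE)))
    singular <- lme4::isSingular(fit, tol = 1e-5)
    if (singular) {
      f1 <- lm(as.formula(paste("y ~", rhs)), data = d)
      f0 <- lm(as.formula(paste("y ~", rhs0)), data = d)
      av <- anova(f0, f1)
      tcoef <- grep(paste0("^", term), names(coef(f1)), value = TRUE)[1]
      eff <- coef(f1)[[tcoef]]
      se <- sqrt(diag(vcov(f1)))[[tcoef]]
      p <- av$`Pr(>F)`[2]
      dfl <- av$Df[2]
    } else {
      m1 <- suppressMessages(suppressWarnings(
        lme4::lmer(as.formula(paste("y ~", rhs, "+ (1|donor_id)")),
                   data = d, REML = FALSE)))
      m0 <- suppressMessages(suppressWarnings(
        lme4::lmer(as.formula(paste("y ~", rhs0, "+ (1|donor_id)")),
                   data = d, REML = FALSE)))
      lrt <- 2 * (as.numeric(logLik(m1)) - as.numeric(logLik(m0)))
      dfl <- attr(logLik(m1), "df") - attr(logLik(m0), "df")
      p <- pchisq(max(lrt, 0), df = dfl, lower.tail = FALSE)
      fe <- lme4::fixef(fit)
      tcoef <- grep(paste0("^", term), names(fe), value = TRUE)[1]
      eff <- fe[[tcoef]]
      se <- sqrt(diag(as.matrix(vcov(fit))))[[match(tcoef, names(fe))]]
    }
    out[[i]] <- tibble(site_id = rownames(beta)[i], effect = eff * 100,
                       se = se * 100, p_lrt = p, log10_p = log10(max(p, 1e-320)),
                       df_lrt = dfl, singular_fallback = singular)
  }
  bind_rows(out) |> mutate(significant = .data$p_lrt < alpha)
}

#' Compare site effects between life stages
#'
#' Correlates per-site age effects estimated in two cohorts (e.g.
#' prenatal vs postnatal cortex) over their shared sites and classifies
#' sites by sign agreement among those significant in the second cohort.
#'
#' @param res_a,res_b Site-result tibbles from [fit_dmps()] (effects per
#'   week and per year are compared as-is; correlation is scale-free).
#' @param alpha_b Significance threshold applied to cohort B p-values
#'   for the sign-agreement classification.
#' @return List: `correlation` (Pearson over shared sites), `sites`
#'   (tibble with `class` in consistent/opposite/b-null), `summary`
#'   (counts and the opposite-direction percentage).
#' @export
crossstage_compare <- function(res_a, res_b, alpha_b = 0.05) {
  shared <- dplyr::inner_join(
    res_a |> select("site_id", effect_a = "effect"),
    res_b |> select("site_id", effect_b = "effect", p_b = "p"),
    by = "site_id")
  if (!nrow(shared)) mt_abort("no shared sites between result tables")
  r <- cor(shared$effect_a, shared$effect_b)
  shared <- shared |>
    mutate(class = dplyr::case_when(
      .data$p_b >= alpha_b ~ "b-null",
      sign(.data$effect_a) == sign(.data$effect_b) ~ "consistent",
      TRUE ~ "opposite"))
  n_sig <- sum(shared$class != "b-null")
  n_opp <- sum(shared$class == "opposite")
  list(correlation = r, sites = shared,
       summary = tibble(n_shared = nrow(shared), n_significant = n_sig,
                        n_opposite = n_opp,
                        pct_opposite = ifelse(n_sig > 0, 100 * n_opp / n_sig, NA_real_)))
}

#' Compare per-site variance between two sample groups
#'
#' Computes each site's sample variance on the percentage scale within
#' two groups (e.g. fetal vs adult cortex) and contrasts the per-site
#' variances with a Welch t-test across sites.
#'
#' @param beta_a,beta_b Beta matrices over the same sites (>= 2 samples
#'   each).
#' @param sites Optional site subset.
#' @return List: `per_site` tibble (`var_a`, `var_b` in %^2), `summary`
#'   with mean variances, mean SDs (%), Welch `t`, `p`.
#' @export
variance_compare <- function(beta_a, beta_b, sites = NULL) {
  if (ncol(beta_a) < 2 || ncol(beta_b) < 2)
    mt_abort("variance_compare needs >= 2 samples per group")
  if (!is.null(sites)) {
    beta_a <- beta_a[sites, , drop = FALSE]
    beta_b <- beta_b[sites, , drop = FALSE]
  }
  common <- intersect(rownames(beta_a), rownames(beta_b))
  if (!length(common)) mt_abort("no shared sites between groups")
  va <- apply(beta_a[common, , drop = FALSE] * 100, 1, var, na.rm = TRUE)
  vb <- apply(beta_b[common, , drop = FALSE] * 100, 1, var, na.rm = TRUE)
  tt <- welch_t(va, vb)
  list(per_site = tibble(site_id = common, var_a = unname(va), var_b = unname(vb)),
       summary = tibble(mean_var_a = mean(va), mean_var_b = mean(vb),
                        mean_sd_a = mean(sqrt(va)), mean_sd_b = mean(sqrt(vb)),
                        t = tt$t, df = tt$df, p = 10^tt$log10_p,
                        log10_p = tt$log10_p))
}
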