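# Paired-fraction simulator: each donor contributes one sample per
# fraction; per-site slopes can differ by fraction and donors can carry
# a shared offset.
make_paired <- function(n_donors = 20, slopes = c(`SATB2+` = -4, `SATB2-` = 0),
                        donor_sd = 0, noise_sd = 0.02, n_sites = 1,
                        frac_shift = 0, seed = 1) {
  set.seed(seed)
  frs <- names(slopes)
  age <- runif(n_donors, 8, 20)
  sheet <- tibble::tibble(
    sample_id = sprintf("D%02d_%s", rep(seq_len(n_donors), each = 2),
                        rep(c("p", "m"), n_donors)),
    age_value = rep(age, each = 2), age_unit = "pcw",
    sex = rep(sample(c("M", "F"), n_donors, replace = TRUE), each = 2),
    batch = "B1",
    donor_id = sprintf("D%02d", rep(seq_len(n_donors), each = 2)),
    fraction = rep(frs, n_donors), stage = "prenatal")
  doff <- rep(rnorm(n_donors, 0, donor_sd), each = 2)
  b <- matrix(NA_real_, n_sites, nrow(sheet))
  for (i in seq_len(n_sites)) {
    mu <- 0.5 + (slopes[sheet$fraction] / 100) * (sheet$age_value - 8) +
      ifelse(sheet$fraction == frs[2], frac_shift, 0)
    b[i, ] <- pmin(pmax(mu + doff + rnorm(nrow(sheet), 0, noise_sd), 0.001), 0.999)
  }
  rownames(b) <- sprintf("cg%05d", seq_len(n_sites))
  colnames(b) <- sheet$sample_id
  list(beta = b, sheet = sheet)
}

test_that("interaction model flags differential slopes and recovers strata", {
  d <- make_paired(n_donors = 30, slopes = c(`SATB2+` = -4, `SATB2-` = 0),
                   noise_sd = 0.01, seed = 2)
  res <- fit_interaction(d$beta, d$sheet, covariates = "sex")
  expect_true(res$significant)
  expect_equal(res$`effect_SATB2+`, -4, tolerance = 0.5)
  expect_equal(res$`effect_SATB2-`, 0, tolerance = 0.5)
  expect_equal(abs(res$interaction_effect), 4, tolerance = 0.5)
})

test_that("equal slopes give a near-zero interaction", {
  d <- make_paired(n_donors = 30, slopes = c(`SATB2+` = -2, `SATB2-` = -2),
                   noise_sd = 0.01, seed = 3)
  res <- fit_interaction(d$beta, d$sheet, covariates = "sex")
  expect_false(res$significant)
  expect_lt(abs(res$interaction_effect), 3 * res$interaction_se)
})

test_that("interaction model rejects a fraction with too few samples", {
  d <- make_paired(n_donors = 10, seed = 4)
  keep <- c(which(d$sheet$fraction == "SATB2+"),
            which(d$sheet$fraction == "SATB2-")[1:2])
  expect_error(fit_interaction(d$beta[, keep, drop = FALSE], d$sheet[keep, ]),
               "fewer than 3")
})

test_that("mixed model collapses to OLS when donor variance is zero", {
  d <- make_paired(n_donors = 15, slopes = c(`SATB2+` = 0, `SATB2-` = 0),
                   donor_sd = 0, noise_sd = 0.03, frac_shift = 0.05, seed = 5)
  res <- fit_site_mixed(d$beta, d$sheet, covariates = c("age_value", "sex"))
  f1 <- lm(d$beta[1, ] ~ d$sheet$age_value + d$sheet$sex +
             factor(d$sheet$fraction))
  cf <- grep("fraction", names(coef(f1)), value = TRUE)
  ols_eff <- coef(f1)[[cf]] * 100
  if (res$singular_fallback) {
    expect_equal(res$effect, ols_eff, tolerance = 1e-6)
  } else {
    # near-zero fitted donor variance: estimates agree closely anyway
    expect_equal(res$effect, ols_eff, tolerance = 0.05)
  }
})

test_that("mixed model gains power from strong donor offsets in a paired design", {
  d <- make_paired(n_donors = 20, slopes = c(`SATB2+` = 0, `SATB2-` = 0),
                   donor_sd = 0.08, noise_sd = 0.01, frac_shift = 0.02, seed = 6)
  mm <- fit_site_mixed(d$beta, d$sheet, covariates = c("age_value", "sex"))
  # OLS on the same data: fraction term tested against total variance
  f1 <- lm(d$beta[1, ] ~ d$sheet$age_value + d$sheet$sex + factor(d$sheet$fraction))
  cf <- grep("fraction", rownames(summary(f1)$coefficients), value = TRUE)
  p_ols <- summary(f1)$coefficients[cf, 4]
  expect_false(mm$singular_fallback)
  expect_lt(mm$p_lrt, p_ols)
})

test_that("mixed-model LRT p-values are near-uniform under the null", {
  d <- make_paired(n_donors = 15, slopes = c(`SATB2+` = 0, `SATB2-` = 0),
                   donor_sd = 0.04, noise_sd = 0.03, n_sites = 300, seed = 7)
  res <- fit_site_mixed(d$beta, d$sheet, covariates = c("age_value", "sex"))
  ks <- suppressWarnings(ks.test(res$p_lrt, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(mean(res$p_lrt < 0.05), 0.12)
})

test_that("cross-stage comparison classifies sign agreement", {
  res <- tibble::tibble(site_id = paste0("cg", 1:50),
                        effect = rnorm(50), p = rep(1e-10, 50))
  cc <- crossstage_compare(res, res, alpha_b = 0.05)
  expect_equal(cc$correlation, 1)
  expect_true(all(cc$sites$class == "consistent"))

  neg <- dplyr::mutate(res, effect = -effect)
  cc2 <- crossstage_compare(res, neg, alpha_b = 0.05)
  expect_equal(cc2$correlation, -1)
  expect_true(all(cc2$sites$class == "opposite"))
  expect_equal(cc2$summary$pct_opposite, 100)
})

test_that("variance comparison recovers planted group variances", {
  z <- matrix(rnorm(50 * 30, 0.5, 0.02), 50, 30)
  b <- make_beta(z)
  same <- variance_compare(b, b)
  expect_equal(same$summary$mean_var_a, same$summary$mean_var_b)
  expect_equal(same$summary$t, 0, tolerance = 1e-12)

  # planted variances 120 and 41.7 on the percentage scale
  set.seed(9)
  a <- make_beta(matrix(rnorm(400 * 60, 0.5, sqrt(120) / 100), 400, 60))
  b2 <- a; b2[] <- rnorm(length(a), 0.5, sqrt(41.7) / 100)
  vc <- variance_compare(a, b2)
  expect_equal(vc$summary$mean_var_a, 120, tolerance = 120 * 0.05)
  expect_equal(vc$summary$mean_var_b, 41.7, tolerance = 41.7 * 0.05)
  expect_lt(vc$summary$p, 1e-10)

  expect_error(variance_compare(a[, 1, drop = FALSE], b2), ">= 2 samples")
})
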