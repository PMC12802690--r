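test_that("per-site OLS matches the closed-form oracle", {
  # 5-point single-covariate worked example
  age <- c(6, 9, 12, 15, 18)
  y <- c(0.20, 0.24, 0.25, 0.31, 0.33)
  b <- make_beta(matrix(y, 1, 5))
  sheet <- make_sheet(5, age = age)
  res <- fit_dmps(b, sheet, covariates = character(0), min_n = 5)
  or <- ols_oracle(y, cbind(1, age), 2)
  expect_equal(res$effect, or$effect * 100, tolerance = 1e-10)
  expect_equal(res$se, or$se * 100, tolerance = 1e-10)
  expect_equal(res$t, unname(or$t), tolerance = 1e-10)
  expect_equal(res$p, unname(or$p), tolerance = 1e-10)

  # property: any small instance with covariates matches the oracle
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:6, 1)
    age <- runif(n, 6, 23)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    if (length(unique(sex)) == 1) sex[1] <- setdiff(c("M", "F"), sex[1])
    y <- runif(n, 0.2, 0.8)
    b <- make_beta(matrix(y, 1, n))
    sheet <- make_sheet(n, age = age, sex = sex, batch = rep("B1", n))
    res <- fit_dmps(b, sheet, covariates = "sex", min_n = 5)
    X <- cbind(1, age, as.numeric(factor(sex)) - 1)
    or <- ols_oracle(y, X, 2)
    expect_equal(res$effect / 100, unname(or$effect), tolerance = 1e-10)
    expect_equal(res$se / 100, unname(or$se), tolerance = 1e-10)
  }
})

test_that("a noiseless linear site is recovered and flagged as a dDMP", {
  sheet <- make_sheet(20)
  mu <- 0.2 + 0.01 * (sheet$age_value - 6)
  b <- make_beta(matrix(mu, 1, 20))
  res <- fit_dmps(b, sheet, covariates = character(0))
  expect_equal(res$effect, 1, tolerance = 1e-6)
  expect_true(res$dmp)
  expect_equal(res$direction, "hyper")
  expect_lt(res$log10_p, -30)
})

test_that("missing values are handled per site by complete cases", {
  set.seed(3)
  sheet <- make_sheet(30)
  b <- make_beta(matrix(runif(60, 0.3, 0.7), 2, 30))
  b[2, c(4, 9)] <- NA
  res <- fit_dmps(b, sheet, covariates = "sex")
  expect_equal(res$n_used, c(30L, 28L))
  ok <- !is.na(b[2, ])
  sub <- fit_dmps(make_beta(b[2, ok, drop = FALSE]), sheet[ok, ], covariates = "sex")
  expect_equal(res$effect[2], sub$effect, tolerance = 1e-12)
})

test_that("a rank-deficient design is rejected with the collinear column named", {
  sheet <- make_sheet(12, sex = rep(c("M", "F"), 6), batch = rep(c("B1", "B2"), 6))
  b <- make_beta(matrix(runif(12, 0.3, 0.7), 1, 12))
  expect_error(fit_dmps(b, sheet, covariates = c("sex", "batch")),
               "rank deficient.*batch")
})

test_that("permuted-age null holds its empirical type-I error", {
  set.seed(101)
  n <- 40
  sheet <- make_sheet(n, age = sample(seq(6, 23, length.out = n)))
  b <- make_beta(matrix(rnorm(1000 * n, 0.5, 0.05), 1000, n))
  res <- fit_dmps(b, sheet, covariates = character(0))
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("direction binomial test matches exact enumeration and closed forms", {
  d <- direction_binomial(c(rep(-1, 5), rep(1, 5)), success = "hypo", p0 = 0.5)
  expect_equal(d$p_one_tailed, 638 / 1024, tolerance = 1e-12)

  # all successes: tail is p0^n
  d2 <- direction_binomial(rep(-1, 12), success = "hypo", p0 = 0.4)
  expect_equal(d2$p_one_tailed, 0.4^12, tolerance = 1e-12)

  # enumeration oracle for n <= 20
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(3:20, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.2, 0.8)
    lp <- binom_tail(k, n, p0, "greater")
    expect_equal(exp(lp), binom_tail_enum(k, n, p0), tolerance = 1e-10)
  }
})

test_that("effect-magnitude comparison behaves at the null and under separation", {
  same <- rnorm(50, 1, 0.1)
  r0 <- compare_effect_magnitude(same, -same)
  expect_equal(r0$t, 0, tolerance = 1e-12)
  expect_equal(r0$p, 1, tolerance = 1e-12)

  set.seed(5)
  a <- rnorm(500, 1.0, 0.1); b <- rnorm(500, 1.5, 0.1)
  r1 <- compare_effect_magnitude(a, -b)
  expect_lt(r1$p, 1e-10)
  # Welch oracle
  va <- var(a) / 500; vb <- var(b) / 500
  expect_equal(r1$t, (mean(a) - mean(b)) / sqrt(va + vb), tolerance = 1e-10)

  expect_error(compare_effect_magnitude(numeric(0), b), "non-empty")
})

test_that("global trend recovers planted drift and respects symmetry", {
  sheet <- make_sheet(40)
  flat <- make_beta(matrix(rep(seq(0.3, 0.7, length.out = 50), 40), 50, 40))
  g0 <- global_trend(flat, sheet, covariates = character(0))
  expect_equal(g0$effect, 0, tolerance = 1e-8)

  # equal and opposite slopes cancel exactly
  up <- outer(rep(0.005, 25), sheet$age_value - 6) + 0.4
  dn <- -outer(rep(0.005, 25), sheet$age_value - 6) + 0.6
  sym <- make_beta(rbind(up, dn))
  gs <- global_trend(sym, sheet, covariates = character(0))
  expect_equal(gs$effect, 0, tolerance = 1e-8)

  # planted global drift of -0.02 pp/week recovered within its SE
  set.seed(21)
  drift <- outer(rep(-0.0002, 200), sheet$age_value - 6) + 0.5 +
    matrix(rnorm(200 * 40, 0, 0.02), 200, 40)
  gd <- global_trend(make_beta(drift), sheet, covariates = character(0))
  expect_lt(abs(gd$effect - (-0.02)), 2 * gd$se + 0.01)
})

test_that("reported percentage arithmetic rounds to three significant figures", {
  expect_equal(signif(100 * 50913 / 807806, 3), 6.30)
  expect_equal(signif(100 * 50329 / 50913, 3), 98.9)
})
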