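# Shared fixture builders; everything is generated in code at test time.

# Minimal sample sheet for a hand-built beta matrix.
make_sheet <- function(n, age = seq(6, 23, length.out = n),
                       sex = rep(c("M", "F"), length.out = n),
                       batch = rep(c("B1", "B1", "B2"), length.out = n),
                       fraction = "bulk") {
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    age_value = age, age_unit = "pcw", sex = sex, batch = batch,
    donor_id = sprintf("D%03d", seq_len(n)), fraction = fraction,
    stage = "prenatal")
}

# Beta matrix from a numeric matrix, adding dimnames.
make_beta <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%05d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("S%03d", seq_len(ncol(m)))
  m
}

# Closed-form OLS oracle: slope, se and two-sided p for one column of X.
ols_oracle <- function(y, X, j) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * XtXi[j, j])
  t <- b[j] / se
  list(effect = b[j], se = se, t = t, p = 2 * pt(-abs(t), df), df = df)
}

# Dense-matrix GP log-marginal-likelihood oracle (explicit inverse and
# determinant; independent of the package's Cholesky path).
gp_oracle <- function(x, y, kernel) {
  n <- length(x)
  K <- matrix(kernel$sigma_b2, n, n)
  if (kernel$kind == "linear") K <- K + kernel$sigma_v2 * outer(x, x)
  if (kernel$kind == "matern52") {
    r <- abs(outer(x, x, "-"))
    a <- sqrt(5) * r / kernel$lengthscale
    K <- K + kernel$sigma_f2 * (1 + a + a^2 / 3) * exp(-a)
  }
  K <- K + diag(kernel$sigma_n2, n)
  -0.5 * drop(t(y) %*% solve(K) %*% y) -
    0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    n / 2 * log(2 * pi)
}

# Exact one-tailed binomial upper tail by direct enumeration (log space).
binom_tail_enum <- function(k, n, p0) {
  if (k == 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log(1 - p0)))
}
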