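#' Exact Gaussian-process marginal log-likelihood
#'
#' Evaluates the log marginal likelihood of centred methylation values
#' under a zero-mean GP,
#' L = -1/2 y' K^-1 y - 1/2 log|K| - (n/2) log 2pi,
#' where K is the kernel's covariance plus the noise term sigma_n^2 I.
#' Three kernels are supported, each containing a bias (constant
#' offset) and noise term so that the constant model is nested in both
#' alternatives:
#' \describe{
#'   \item{constant}{K = sigma_b^2 J + sigma_n^2 I}
#'   \item{linear}{adds sigma_v^2 x x' (a Bayesian straight line with
#'     free intercept once y is centred; x in raw pcw units)}
#'   \item{matern52}{adds the Matern 5/2 covariance
#'     sigma_f^2 (1 + sqrt5 r/l + 5 r^2/(3 l^2)) exp(-sqrt5 r/l) with
#'     lengthscale (timescale) l in pcw}
#' }
#' Computation uses a Cholesky factorisation with a jitter ladder
#' (1e-10 to 1e-6 of the mean diagonal); if K remains non-PD the
#' -Inf sentinel is returned.
#'
#' @param x Ages in post-conception weeks.
#' @param y Centred methylation values (same length, no NAs).
#' @param kernel A list: `kind` in `"constant"`, `"linear"`,
#'   `"matern52"`; variances `sigma_b2`, `sigma_n2`, plus `sigma_v2`
#'   (linear) or `sigma_f2` and `lengthscale` (matern52).
#' @return The log marginal likelihood (scalar).
#' @export
gp_marginal_loglik <- function(x, y, kernel) {
  if (any(!is.finite(y))) mt_abort("y must be finite")
  if (length(x) != length(y)) mt_abort("x and y lengths differ")
  if (length(y) < 3) mt_abort("need at least 3 observations")
  K <- gp_cov(x, kernel)
  gp_loglik_chol(K, y)$L
}

# Covariance matrix for a kernel spec.
gp_cov <- function(x, kernel) {
  n <- length(x)
  K <- matrix(kernel$sigma_b2, n, n)
  if (kernel$kind == "linear") {
    K <- K + kernel$sigma_v2 * tcrossprod(x)
  } else if (kernel$kind == "matern52") {
    r <- abs(outer(x, x, "-"))
    a <- sqrt(5) * r / kernel$lengthscale
    K <- K + kernel$sigma_f2 * (1 + a + a^2 / 3) * exp(-a)
  } else if (kernel$kind != "constant") {
    mt_abort("unknown kernel kind '%s'", kernel$kind)
  }
  K + diag(kernel$sigma_n2, n)
}

# Cholesky with jitter ladder; returns L (loglik), alpha = K^-1 y and the
# factor, or L = -Inf when K cannot be factorised.
gp_loglik_chol <- function(K, y) {
  n <- length(y)
  jit <- c(0, 10^seq(-10, -6))
  scale <- mean(diag(K))
  for (j in jit) {
    ch <- tryCatch(chol(K + diag(j * scale, n)), error = function(e) NULL)
    if (!is.null(ch)) {
      alpha <- backsolve(ch, forwardsolve(t(ch), y))
      L <- -0.5 * sum(y * alpha) - sum(log(diag(ch))) - 0.5 * n * log(2 * pi)
      return(list(L = L, alpha = alpha, chol = ch))
    }
  }
  list(L = -Inf, alpha = NULL, chol = NULL)
}

# Hyperparameter layout per kind (all optimized on the log scale).
gp_par_names <- function(kind) {
  switch(kind,
         constant = c("sigma_b2", "sigma_n2"),
         linear = c("sigma_b2", "sigma_v2", "sigma_n2"),
         matern52 = c("sigma_b2", "sigma_f2", "lengthscale", "sigma_n2"),
         mt_abort("unknown kernel kind '%s'", kind))
}

gp_bounds <- function(kind) {
  nm <- gp_par_names(kind)
  # variance floor well below any data scale: with uncentered x (pcw up
  # to ~25), a floor of 1e-8 on sigma_v2 still contributes visible
  # covariance (~1e-8 * 625) and breaks the nested-model ordering
  lo <- ifelse(nm == "lengthscale", 0.5, 1e-12)
  hi <- ifelse(nm == "lengthscale", 200, 10)
  list(lower = log(lo), upper = log(hi), names = nm)
}

# Negative log marginal likelihood and its gradient w.r.t. log-params.
gp_objective <- function(logp, kind, x, y, r = NULL) {
  p <- as.list(exp(logp))
  names(p) <- gp_par_names(kind)
  p$kind <- kind
  n <- length(y)
  K <- matrix(p$sigma_b2, n, n)
  if (kind == "linear") K <- K + p$sigma_v2 * tcrossprod(x)
  if (kind == "matern52") {
    if (is.null(r)) r <- abs(outer(x, x, "-"))
    a <- sqrt(5) * r / p$lengthscale
    E <- exp(-a)
    M <- (1 + a + a^2 / 3) * E
    K <- K + p$sigma_f2 * M
  }
  K <- K + diag(p$sigma_n2, n)
  lc <- gp_loglik_chol(K, y)
  if (!is.finite(lc$L)) return(list(value = 1e10, gradient = rep(0, length(logp))))
  alpha <- lc$alpha
  Kinv <- chol2inv(lc$chol)
  # dL/dtheta = 1/2 tr((alpha alpha' - K^-1) dK/dtheta); theta = log-param
  A <- tcrossprod(alpha) - Kinv
  gr <- numeric(length(logp))
  names(gr) <- gp_par_names(kind)
  gr["sigma_b2"] <- 0.5 * p$sigma_b2 * sum(A)
  gr["sigma_n2"] <- 0.5 * p$sigma_n2 * sum(diag(A))
  if (kind == "linear") {
    gr["sigma_v2"] <- 0.5 * p$sigma_v2 * sum(A * tcrossprod(x))
  }
  if (kind == "matern52") {
    gr["sigma_f2"] <- 0.5 * p$sigma_f2 * sum(A * M)
    dM_dlogl <- p$sigma_f2 * E * a^2 * (1 + a) / 3
    gr["lengthscale"] <- 0.5 * sum(A * dM_dlogl)
  }
  list(value = -lc$L, gradient = -gr)
}

#' Fit a GP kernel by marginal-likelihood optimisation
#'
#' Maximises the log marginal likelihood over log-hyperparameters with
#' L-BFGS-B (analytic gradients), using `n_restarts` seeded
#' initialisations drawn log-uniformly within the bounds (variances in
#' \[1e-8, 10\] on the proportion-squared scale, lengthscale in
#' \[0.5, 200\] pcw). Additional initialisations may be supplied to warm
#' start from a simpler model's optimum, which keeps the nested-model
#' log-likelihood ordering numerically clean.
#'
#' @param x Ages (pcw).
#' @param y Methylation values; centred by their mean before fitting.
#' @param kind Kernel kind: `"constant"`, `"linear"`, `"matern52"`.
#' @param n_restarts Number of random restarts.
#' @param seed Integer seed for the restart draws.
#' @param extra_inits Optional list of named natural-scale parameter
#'   vectors used as additional starting points.
#' @return An object of class `meth_gp_fit`: `kind`, `params` (natural
#'   scale), `L` (optimised log marginal likelihood), `converged`,
#'   `restarts_used`, `n_used`.
#' @export
fit_gp <- function(x, y, kind, n_restarts = 5, seed = 1L, extra_inits = NULL) {
  ok <- is.finite(y) & is.finite(x)
  x <- x[ok]; y <- y[ok]
  if (length(y) < 5) mt_abort("fit_gp needs >= 5 observations")
  y <- y - mean(y)
  b <- gp_bounds(kind)
  r <- if (kind == "matern52") abs(outer(x, x, "-")) else NULL
  vy <- max(var(y), 1e-7)

  inits <- list()
  # data-driven first start: split variance between signal/bias and noise
  st <- log(pmin(pmax(setNames(rep(vy / 2, length(b$names)), b$names), exp(b$lower)),
                 exp(b$upper)))
  if (kind == "matern52") st["lengthscale"] <- log(8)
  if (kind == "linear") st["sigma_v2"] <- log(pmin(vy / max(mean(x^2), 1), 10))
  inits[[1]] <- st
  set.seed(child_seed(seed, 101L))
  while (length(inits) < n_restarts) {
    inits[[length(inits) + 1]] <- runif(length(b$names), b$lower, b$upper)
  }
  for (ei in extra_inits %||% list()) {
    v <- log(pmin(pmax(ei[b$names], exp(b$lower)), exp(b$upper)))
    inits[[length(inits) + 1]] <- v
  }

  best <- NULL
  for (init in inits) {
    fit <- tryCatch(
      optim(par = init,
            fn = function(lp) gp_objective(lp, kind, x, y, r)$value,
            gr = function(lp) gp_objective(lp, kind, x, y, r)$gradient,
            method = "L-BFGS-B", lower = b$lower, upper = b$upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(kind = kind, params = NULL, L = -Inf,
                          converged = FALSE, restarts_used = length(inits),
                          n_used = length(y)), class = "meth_gp_fit"))
  }
  params <- setNames(exp(best$par), b$names)
  structure(list(kind = kind, params = params, L = -best$value,
                 converged = TRUE, restarts_used = length(inits),
                 n_used = length(y)),
            class = "meth_gp_fit")
}

#' @export
print.meth_gp_fit <- function(x, ...) {
  cat(sprintf("<meth_gp_fit> kernel=%s  logML=%.3f  n=%d%s\n", x$kind, x$L,
              x$n_used, if (x$converged) "" else "  (not converged)"))
  if (!is.null(x$params)) {
    cat(paste(sprintf("  %s=%.4g", names(x$params), x$params), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Classify one site's methylation trajectory
#'
#' Fits the constant, linear and Matern 5/2 kernels to one site and
#' selects the class with the greatest optimised log marginal
#' likelihood. Ties (differences below 1e-6) are broken towards the
#' simpler model. The linear and Matern fits are warm-started from the
#' constant optimum (nesting), so the log-likelihood ratios against the
#' constant model are non-negative up to optimiser tolerance.
#'
#' Because the constant model is nested in the Matern model, type-II
#' maximum likelihood lets the richer kernel pick up chance
#' autocorrelation in pure noise, so the raw argmax over-calls
#' nonlinear. The `class_refined` column therefore applies the
#' refinement margin at the classification stage: nonlinear only when
#' the log-likelihood ratio against *both* simpler kernels is at least
#' `llr_margin` (default 2, the refinement threshold), otherwise the
#' better of constant and linear.
#'
#' @param x Ages (pcw).
#' @param y One site's methylation values (NAs dropped; centred
#'   internally).
#' @param n_restarts,seed Passed to [fit_gp()].
#' @param llr_margin Margin (log units) the Matern fit must exceed both
#'   simpler fits by for a refined nonlinear call.
#' @return One-row tibble: `L_const`, `L_lin`, `L_nl`, `class`,
#'   `class_refined`, `llr_vs_const`, `llr_vs_lin` (both for the Matern
#'   fit), `timescale` (pcw), `period` (pcw).
#' @export
classify_site <- function(x, y, n_restarts = 5, seed = 1L, llr_margin = 2) {
  fc <- fit_gp(x, y, "constant", n_restarts, seed)
  init_c <- if (fc$converged) {
    list(c(sigma_b2 = unname(fc$params["sigma_b2"]),
           sigma_v2 = 1e-12, sigma_f2 = 1e-12, lengthscale = 8,
           sigma_n2 = unname(fc$params["sigma_n2"])))
  } else NULL
  fl <- fit_gp(x, y, "linear", n_restarts, seed, extra_inits = init_c)
  fm <- fit_gp(x, y, "matern52", n_restarts, seed, extra_inits = init_c)
  Ls <- c(constant = fc$L, linear = fl$L, nonlinear = fm$L)
  # argmax with ties (< 1e-6) towards the simpler model
  best <- which(Ls >= max(Ls) - 1e-6)[1]
  ts <- if (fm$converged) unname(fm$params["lengthscale"]) else NA_real_
  cls <- names(Ls)[best]
  refined <- if (cls == "nonlinear" &&
                 min(fm$L - fc$L, fm$L - fl$L) < llr_margin) {
    if (fl$L >= fc$L + 1e-6) "linear" else "constant"
  } else cls
  tibble(L_const = fc$L, L_lin = fl$L, L_nl = fm$L,
         class = cls, class_refined = refined,
         llr_vs_const = fm$L - fc$L,
         llr_vs_lin = fm$L - fl$L,
         timescale = ts,
         period = timescale_to_period(ts))
}

#' GP trajectory classification over a beta matrix
#'
#' Applies [classify_site()] to every site, using ages from the sample
#' sheet, and appends the high-confidence refinement flag
#' ([refine_nonlinear()]).
#'
#' @param beta Sites x samples beta matrix (QC-filtered; see
#'   [qc_filter()]).
#' @param sheet Sample sheet providing `age_value` in pcw.
#' @param n_restarts,seed Optimiser settings per site.
#' @param llr_min,timescale_min Refinement thresholds.
#' @return A tibble (class `meth_gp_classification`) with one row per
#'   site.
#' @export
classify_sites <- function(beta, sheet, n_restarts = 5, seed = 1L,
                           llr_min = 2, timescale_min = 10, llr_margin = 2) {
  validate_beta_matrix(beta)
  sheet <- validate_sample_sheet(sheet)
  age <- sheet$age_value[match(colnames(beta), sheet$sample_id)]
  rows <- vector("list", nrow(beta))
  for (i in seq_len(nrow(beta))) {
    rows[[i]] <- classify_site(age, beta[i, ], n_restarts = n_restarts,
                               seed = child_seed(seed, i),
                               llr_margin = llr_margin)
  }
  out <- bind_rows(rows)
  out <- dplyr::bind_cols(tibble(site_id = rownames(beta)), out)
  out <- refine_nonlinear(out, llr_min = llr_min, timescale_min = timescale_min)
  class(out) <- c("meth_gp_classification", class(out))
  out
}

#' Refine nonlinear calls to a high-confidence set
#'
#' A site is high-confidence nonlinear when its class is nonlinear, its
#' log-likelihood ratio against *both* the constant and the linear
#' kernels is at least `llr_min`, and its timescale is at least
#' `timescale_min` pcw (both bounds inclusive). Sites oscillating
#' faster than ~10 pcw are biologically implausible on this sampling
#' grid and are excluded.
#'
#' @param classifications Tibble from [classify_sites()] (or
#'   [classify_site()] rows).
#' @param llr_min Minimum LLR against both simpler kernels.
#' @param timescale_min Minimum Matern lengthscale (pcw).
#' @return The input with a `high_confidence` logical column
#'   (re)computed.
#' @export
refine_nonlinear <- function(classifications, llr_min = 2, timescale_min = 10) {
  classifications$high_confidence <-
    classifications$class == "nonlinear" &
    pmin(classifications$llr_vs_const, classifications$llr_vs_lin) >= llr_min &
    !is.na(classifications$timescale) &
    classifications$timescale >= timescale_min
  classifications
}

#' Convert a Matern timescale to an oscillation period
#'
#' The Matern 5/2 lengthscale ("timescale", pcw) maps to the period of
#' one complete oscillation as period = 2 pi sqrt(3/5) x timescale
#' (~4.87, i.e. a timescale of 1 oscillates roughly every 5 pcw).
#'
#' @param timescale Lengthscale in pcw.
#' @return Period in pcw.
#' @export
#' @examples
#' timescale_to_period(1) # ~4.87
timescale_to_period <- function(timescale) {
  2 * pi * sqrt(3 / 5) * timescale
}

#' @export
tidy.meth_gp_fit <- function(x, ...) {
  if (is.null(x$params)) {
    return(tibble(term = character(), estimate = numeric()))
  }
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.meth_gp_fit <- function(x, ...) {
  tibble(kind = x$kind, logLik = x$L, converged = x$converged,
         n = x$n_used, restarts = x$restarts_used)
}
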