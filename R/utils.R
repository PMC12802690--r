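# Internal helpers shared across modules.

# Abort with a consistent class so tests can target methtraj errors.
mt_abort <- function(msg, ...) {
  rlang::abort(message = sprintf(msg, ...), class = "methtraj_error")
}

mt_warn <- function(msg, ...) {
  rlang::warn(message = sprintf(msg, ...), class = "methtraj_warning")
}

# Clip proportions away from the exact bounds used by the simulator.
clip01 <- function(x, lo = 0.001, hi = 0.999) {
  pmin(pmax(x, lo), hi)
}

# log10 of an upper-tail probability given the natural-log tail; keeps
# extreme p-values representable (carried in log10 space, printed late).
log_to_log10 <- function(logp) logp / log(10)

# Format a p carried as log10 for display; values below the smallest
# representable double print as "<1e-320".
format_log10p <- function(log10p) {
  ifelse(log10p < -320, "<1e-320", sprintf("%.3g", 10^log10p))
}

# Deterministic child seed: derive per-task seeds from one user seed while
# staying inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k * 9973) %% 2147483647L)
}

# Dirichlet draws via independent gammas.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
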