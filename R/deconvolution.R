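#' Select reference probes that discriminate cell types
#'
#' For each cell type, computes one-vs-rest Welch t-statistics at every
#' site of a purified-sample beta matrix and keeps the top `num_probes`
#' by absolute t regardless of sign (`probe_select = "any"`), ties
#' broken by site_id. The reference matrix holds each cell type's mean
#' methylation over the union of selected sites.
#'
#' @param beta Purified-sample beta matrix (sites x samples).
#' @param cell_labels Cell-type label per column of `beta`; >= 2 types
#'   with >= 2 samples each.
#' @param num_probes Probes selected per cell type (default 100); if
#'   fewer candidates exist, all are taken with a warning.
#' @param probe_select Only `"any"` (top by |t|) is implemented.
#' @return Object of class `meth_reference`: `profiles` (selected sites
#'   x cell types matrix of means), `selected` (tibble: cell_type,
#'   site_id, t).
#' @export
select_reference_probes <- function(beta, cell_labels, num_probes = 100,
                                    probe_select = "any") {
  if (probe_select != "any") mt_abort("only probe_select = 'any' is implemented")
  cts <- sort(unique(cell_labels))
  if (length(cts) < 2) mt_abort("need >= 2 cell types")
  if (any(table(cell_labels) < 2)) mt_abort("need >= 2 samples per cell type")
  if (num_probes > nrow(beta)) {
    mt_warn("fewer candidate sites (%d) than num_probes; taking all", nrow(beta))
    num_probes <- nrow(beta)
  }
  sel <- lapply(cts, function(ct) {
    g1 <- cell_labels == ct
    m1 <- rowMeans(beta[, g1, drop = FALSE])
    m2 <- rowMeans(beta[, !g1, drop = FALSE])
    v1 <- apply(beta[, g1, drop = FALSE], 1, var)
    v2 <- apply(beta[, !g1, drop = FALSE], 1, var)
    t <- (m1 - m2) / sqrt(pmax(v1 / sum(g1) + v2 / sum(!g1), 1e-12))
    ord <- order(-abs(t), rownames(beta))
    idx <- ord[seq_len(num_probes)]
    tibble(cell_type = ct, site_id = rownames(beta)[idx], t = t[idx])
  })
  sel <- bind_rows(sel)
  sites <- sort(unique(sel$site_id))
  profiles <- sapply(cts, function(ct)
    rowMeans(beta[sites, cell_labels == ct, drop = FALSE]))
  rownames(profiles) <- sites
  structure(list(profiles = profiles, selected = sel),
            class = "meth_reference")
}

#' Estimate cell-type proportions in bulk samples
#'
#' Solves, per bulk sample, the non-negative least-squares projection
#' min ||y - X w||_2 subject to w >= 0 over the reference sites (no
#' sum-to-one constraint; the proportion sum is reported as a
#' diagnostic), and scores reconstruction quality with the CETYGO-style
#' root-mean-square error ([cetygo_score()]).
#'
#' @param bulk Bulk beta matrix (sites x samples); at least 50% of the
#'   reference sites must be present.
#' @param reference A `meth_reference` or a sites x cell-types profile
#'   matrix.
#' @return Object of class `meth_deconv`: a tibble with `sample_id`,
#'   one proportion column per cell type, `proportion_sum`, `cetygo`,
#'   and the attribute `n_sites_used`.
#' @export
estimate_proportions <- function(bulk, reference) {
  X0 <- if (inherits(reference, "meth_reference")) reference$profiles else reference
  common <- intersect(rownames(X0), rownames(bulk))
  if (length(common) < 0.5 * nrow(X0))
    mt_abort("only %d of %d reference sites present in the bulk matrix",
             length(common), nrow(X0))
  X <- X0[common, , drop = FALSE]
  if (qr(X)$rank < ncol(X)) mt_abort("reference matrix is rank deficient")
  out <- lapply(colnames(bulk), function(s) {
    y <- bulk[common, s]
    ok <- !is.na(y)
    w <- pracma::lsqnonneg(X[ok, , drop = FALSE], y[ok])$x
    names(w) <- colnames(X)
    row <- as_tibble(as.list(w))
    row$sample_id <- s
    row$proportion_sum <- sum(w)
    row$cetygo <- cetygo_score(y[ok], X[ok, , drop = FALSE], w)
    row
  })
  res <- bind_rows(out) |>
    select("sample_id", dplyr::everything())
  attr(res, "n_sites_used") <- length(common)
  class(res) <- c("meth_deconv", class(res))
  res
}

#' Root-mean-square reconstruction error of a deconvolution
#'
#' The CETYGO-style score: sqrt of the mean squared difference between
#' the observed bulk profile and its reconstruction from estimated
#' proportions times reference profiles, over the reference sites. Zero
#' for an exact mixture; grows with noise and with reference
#' misspecification (e.g. a missing cell type).
#'
#' @param y Observed bulk values over the reference sites.
#' @param X Reference profile matrix (sites x cell types).
#' @param w Estimated proportions.
#' @return Non-negative scalar.
#' @export
cetygo_score <- function(y, X, w) {
  r <- y - drop(X %*% w)
  sqrt(mean(r^2))
}

#' @export
tidy.meth_deconv <- function(x, ...) {
  ct <- setdiff(names(x), c("sample_id", "proportion_sum", "cetygo"))
  tidyr::pivot_longer(as_tibble(x)[, c("sample_id", ct)],
                      cols = dplyr::all_of(ct),
                      names_to = "cell_type", values_to = "proportion")
}

#' @export
glance.meth_deconv <- function(x, ...) {
  tibble(n_samples = nrow(x),
         n_sites_used = attr(x, "n_sites_used"),
         mean_cetygo = mean(x$cetygo),
         mean_proportion_sum = mean(x$proportion_sum))
}

#' @export
print.meth_reference <- function(x, ...) {
  cat(sprintf("<meth_reference> %d sites x %d cell types\n",
              nrow(x$profiles), ncol(x$profiles)))
  invisible(x)
}
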