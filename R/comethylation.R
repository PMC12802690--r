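#' Signed co-methylation network and topological overlap
#'
#' Builds a signed weighted adjacency over sites,
#' a_ij = ((1 + cor(x_i, x_j)) / 2)^power (so perfectly anti-correlated
#' sites get weight 0), and converts it to the topological overlap
#' matrix TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)
#' with unit diagonal, where k_i is site i's connectivity.
#'
#' @param beta Sites x samples beta matrix (>= 20 sites, >= 10 samples
#'   recommended); correlation is Pearson on the proportion scale.
#' @param power Soft-threshold exponent (default 12, the standard signed
#'   network choice at this sample size).
#' @return A symmetric sites x sites TOM matrix with entries in \[0,1\].
#' @export
build_network <- function(beta, power = 12) {
  v <- apply(beta, 1, var, na.rm = TRUE)
  if (any(v < 1e-12))
    mt_abort("zero-variance site: %s", rownames(beta)[which(v < 1e-12)[1]])
  cr <- cor(t(beta), use = "pairwise.complete.obs")
  A <- ((1 + cr) / 2)^power
  diag(A) <- 0
  k <- rowSums(A)
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  TOM <- num / den
  diag(TOM) <- 1
  dimnames(TOM) <- list(rownames(beta), rownames(beta))
  TOM
}

#' Detect co-methylation modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM
#' with a static tree cut at `cut_height`; clusters smaller than
#' `min_module_size` are labelled `"unassigned"` (the grey-equivalent,
#' excluded from eigengene and hub computation). Module labels `M1`,
#' `M2`, ... are assigned in decreasing size order, ties broken by first
#' site, so the labelling is deterministic and invariant to input row
#' order.
#'
#' @param TOM Topological overlap matrix from [build_network()].
#' @param min_module_size Smallest cluster kept as a module.
#' @param cut_height Static cut height on the 1 - TOM dendrogram.
#' @return Tibble: `site_id`, `module` (`"M1"`, ..., or
#'   `"unassigned"`).
#' @export
detect_modules <- function(TOM, min_module_size = 30, cut_height = 0.995) {
  d <- as.dist(1 - TOM)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  # order retained clusters by size (desc), then by their first site id
  firsts <- vapply(keep, function(k) min(names(cl)[cl == k]), "")
  ord <- keep[order(-sizes[keep], firsts)]
  lab <- setNames(rep("unassigned", length(sizes)), names(sizes))
  lab[ord] <- paste0("M", seq_along(ord))
  tibble(site_id = names(cl), module = unname(lab[as.character(cl)]))
}

#' Module eigengene
#'
#' First principal component of a module's standardised site x sample
#' matrix, one score per sample, with unit-norm site loadings. The sign
#' is oriented so the mean correlation of member sites with the
#' eigengene (mean kME) is positive.
#'
#' @param beta_module Beta matrix restricted to one module's sites.
#' @return List: `values` (named per-sample scores), `loadings`
#'   (unit-norm per-site), `var_explained` (PC1 share of variance).
#' @export
eigengene <- function(beta_module) {
  Z <- t(scale(t(beta_module)))  # standardise each site across samples
  if (any(!is.finite(Z))) mt_abort("zero-variance or missing site in module")
  sv <- svd(Z)
  scores <- sv$v[, 1] * sv$d[1] / sqrt(max(1, ncol(Z) - 1))
  loadings <- sv$u[, 1]
  kme <- suppressWarnings(cor(t(beta_module), scores))
  if (mean(kme, na.rm = TRUE) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(values = setNames(scores, colnames(beta_module)),
       loadings = setNames(loadings, rownames(beta_module)),
       var_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Eigengenes for every detected module
#'
#' @param beta Full beta matrix.
#' @param assignment Tibble from [detect_modules()].
#' @return Tibble: `module`, `sample_id`, `value`, `var_explained`
#'   (long format; `"unassigned"` sites are excluded).
#' @export
module_eigengenes <- function(beta, assignment) {
  mods <- setdiff(unique(assignment$module), "unassigned")
  out <- lapply(sort(mods), function(m) {
    ids <- assignment$site_id[assignment$module == m]
    eg <- eigengene(beta[ids, , drop = FALSE])
    tibble(module = m, sample_id = names(eg$values),
           value = unname(eg$values), var_explained = eg$var_explained)
  })
  bind_rows(out)
}

#' Hub sites per module
#'
#' A site's kME is its Pearson correlation with its module's eigengene;
#' hub sites are the `top_n` members by kME (ties broken by site_id).
#'
#' @param beta Beta matrix.
#' @param assignment Tibble from [detect_modules()].
#' @param eigengenes Tibble from [module_eigengenes()].
#' @param top_n Number of hubs per module.
#' @return Tibble: `module`, `site_id`, `kme`, `rank`.
#' @export
hub_sites <- function(beta, assignment, eigengenes, top_n = 1) {
  mods <- setdiff(unique(assignment$module), "unassigned")
  out <- lapply(sort(mods), function(m) {
    ids <- assignment$site_id[assignment$module == m]
    eg <- eigengenes |> filter(.data$module == m)
    ev <- setNames(eg$value, eg$sample_id)[colnames(beta)]
    kme <- drop(cor(t(beta[ids, , drop = FALSE]), ev))
    tibble(module = m, site_id = ids, kme = unname(kme)) |>
      arrange(desc(.data$kme), .data$site_id) |>
      mutate(rank = row_number()) |>
      head(top_n)
  })
  bind_rows(out)
}

#' Project one cohort onto another cohort's principal components
#'
#' Performs PCA on the reference cohort (samples as observations, sites
#' centred — and optionally scaled — by reference statistics) and maps
#' the query cohort into the same space using the reference loadings and
#' centering. A query identical to the reference reproduces the
#' reference scores exactly.
#'
#' @param beta_ref,beta_query Beta matrices over the same sites.
#' @param k Number of components returned.
#' @param scale. Scale sites by reference standard deviations.
#' @return List: `reference` and `query` score tibbles (`sample_id`,
#'   `PC1..PCk`, `cohort`), `loadings`, `var_explained`.
#' @export
pca_project <- function(beta_ref, beta_query, k = 2, scale. = TRUE) {
  common <- intersect(rownames(beta_ref), rownames(beta_query))
  if (length(common) < k) mt_abort("too few shared sites for %d components", k)
  Xr <- t(beta_ref[common, , drop = FALSE])
  Xq <- t(beta_query[common, , drop = FALSE])
  pc <- prcomp(Xr, center = TRUE, scale. = scale.)
  k <- min(k, ncol(pc$rotation))
  sc_q <- scale(Xq, center = pc$center,
                scale = if (isTRUE(scale.)) pc$scale else FALSE) %*%
    pc$rotation[, seq_len(k), drop = FALSE]
  as_scores <- function(m, cohort) {
    out <- as_tibble(m[, seq_len(k), drop = FALSE])
    names(out) <- paste0("PC", seq_len(k))
    dplyr::bind_cols(tibble(sample_id = rownames(m), cohort = cohort), out)
  }
  list(reference = as_scores(pc$x, "reference"),
       query = as_scores(sc_q, "query"),
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}
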