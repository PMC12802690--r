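#' Feature and chromosome enrichment of DMPs
#'
#' For each category of the chosen annotation grouping, tests whether
#' DMPs are over- or under-represented with a chi-squared test (no
#' continuity correction) on the 2x2 table of category membership by DMP
#' status. Effects are log odds ratios; when any cell of the table is
#' zero the Haldane correction (+0.5 to every cell) keeps them finite.
#' P-values are Bonferroni-corrected over the categories tested.
#'
#' @param site_results Tibble with `site_id` and logical `dmp`
#'   (e.g. from [fit_dmps()]).
#' @param annotation Probe annotation.
#' @param grouping `"chromosome"`, `"cgi_class"`, or `"genic_class"`.
#' @return Tibble (class `meth_enrichment`): `category`,
#'   `n_in_category`, `n_dmp_in_category`, `effect` (log OR),
#'   `odds_ratio`, `se`, `chisq`, `p`, `p_corrected`.
#' @export
feature_enrichment <- function(site_results, annotation,
                               grouping = c("cgi_class", "genic_class", "chromosome")) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "chromosome") "chrom" else grouping
  d <- dplyr::inner_join(site_results |> select("site_id", "dmp"),
                         annotation |> select("site_id", category = dplyr::all_of(col)),
                         by = "site_id")
  cats <- sort(unique(d$category))
  rows <- lapply(cats, function(cc) {
    inc <- d$category == cc
    a <- sum(inc & d$dmp); b <- sum(inc & !d$dmp)
    cx <- sum(!inc & d$dmp); dx <- sum(!inc & !d$dmp)
    if (a + b == 0) {
      mt_warn("category '%s' has 0 sites; skipped", cc)
      return(NULL)
    }
    tab <- matrix(c(a, b, cx, dx), 2)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
    cells <- c(a, b, cx, dx)
    if (any(cells == 0)) cells <- cells + 0.5
    lor <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
    se <- sqrt(sum(1 / cells))
    tibble(category = cc, n_in_category = a + b, n_dmp_in_category = a,
           effect = lor, odds_ratio = exp(lor), se = se,
           chisq = unname(chi$statistic), p = chi$p.value)
  })
  out <- bind_rows(rows)
  out$p_corrected <- pmin(1, out$p * nrow(out))
  class(out) <- c("meth_enrichment", class(out))
  out
}

#' Direction skew of DMPs within annotation categories
#'
#' Within each category, counts hypermethylated DMPs and applies the
#' one-tailed exact binomial test in the direction of departure, with
#' null success probability `p0` equal (by default) to the
#' hypermethylated proportion across all DMPs genome-wide.
#'
#' @param site_results Tibble with `site_id`, `effect`, `dmp`.
#' @param annotation Probe annotation.
#' @param grouping As in [feature_enrichment()].
#' @param p0 Null hypermethylated proportion; default computed from all
#'   DMPs in `site_results`.
#' @return Tibble: one [direction_binomial()] row per category.
#' @export
direction_by_feature <- function(site_results, annotation,
                                 grouping = c("cgi_class", "genic_class", "chromosome"),
                                 p0 = NULL) {
  grouping <- match.arg(grouping)
  col <- if (grouping == "chromosome") "chrom" else grouping
  dmps <- site_results |> filter(.data$dmp)
  if (!nrow(dmps)) mt_abort("no DMPs to test")
  if (is.null(p0)) p0 <- mean(dmps$effect > 0)
  d <- dplyr::inner_join(dmps |> select("site_id", "effect"),
                         annotation |> select("site_id", category = dplyr::all_of(col)),
                         by = "site_id")
  out <- d |>
    group_by(.data$category) |>
    dplyr::group_modify(function(g, key) {
      if (!nrow(g)) return(tibble())
      direction_binomial(g$effect, success = "hyper", p0 = p0)
    }) |>
    ungroup()
  out$p_corrected <- pmin(1, out$p_one_tailed * nrow(out))
  out
}

#' Open-chromatin peak enrichment of DMPs
#'
#' Annotates every site with binary membership in each cell type's peak
#' set and fits a single joint logistic regression of DMP status on all
#' membership indicators, so each cell type's effect (log-odds) is
#' adjusted for all other cell-type peaks. Wald p-values are
#' Bonferroni-corrected over cell types. Complete separation is flagged
#' and the affected cell type reported with an infinite-effect sentinel
#' and a Fisher exact fallback p.
#'
#' @param site_results Tibble with `site_id`, `dmp`.
#' @param annotation Probe annotation with positions.
#' @param peaks Peak tibble (`cell_type`, `chrom`, `start`, `end`) from
#'   [read_bed()] or [simulate_annotation()].
#' @return Tibble (class `meth_enrichment`): per cell type `effect`,
#'   `odds_ratio`, `se`, `p`, `p_corrected`, `separation`.
#' @export
peak_enrichment <- function(site_results, annotation, peaks) {
  cts <- sort(unique(peaks$cell_type))
  if (length(cts) < 1) mt_abort("no peak sets supplied")
  d <- dplyr::inner_join(site_results |> select("site_id", "dmp"),
                         annotation, by = "site_id")
  M <- sapply(cts, function(ct)
    as.numeric(sites_in_peaks(d, peaks[peaks$cell_type == ct, , drop = FALSE])))
  colnames(M) <- make.names(cts)
  # perfectly collinear membership columns are unidentifiable
  if (ncol(M) > 1) {
    cc <- suppressWarnings(cor(M))
    dup <- which(abs(cc) > 1 - 1e-12 & upper.tri(cc), arr.ind = TRUE)
    if (nrow(dup))
      mt_abort("peak sets '%s' and '%s' are perfectly collinear",
               cts[dup[1, 1]], cts[dup[1, 2]])
  }
  df <- data.frame(dmp = as.numeric(d$dmp), M, check.names = FALSE)
  fit <- suppressWarnings(glm(dmp ~ ., data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  rows <- lapply(seq_along(cts), function(j) {
    nm <- make.names(cts[j])
    est <- sm[nm, "Estimate"]; se <- sm[nm, "Std. Error"]
    p <- sm[nm, "Pr(>|z|)"]
    sep <- !is.finite(est) || abs(est) > 15 || se > 100
    if (sep) {
      tab <- table(factor(M[, nm], levels = c(1, 0)),
                   factor(d$dmp, levels = c(TRUE, FALSE)))
      p <- stats::fisher.test(tab)$p.value
      est <- sign(est) * Inf
      se <- NA_real_
    }
    tibble(category = cts[j],
           n_in_category = sum(M[, nm] == 1),
           n_dmp_in_category = sum(M[, nm] == 1 & d$dmp),
           effect = est, odds_ratio = exp(est), se = se, p = p,
           separation = sep)
  })
  out <- bind_rows(rows)
  out$p_corrected <- pmin(1, out$p * nrow(out))
  class(out) <- c("meth_enrichment", class(out))
  out
}

#' Gene-level DMP table
#'
#' Collapses site-level results to genes: a gene's DMP status is whether
#' at least one of its annotated sites is a DMP, and its size is the
#' number of sites annotated to it. Sites annotated to several genes
#' (semicolon lists) count for every listed gene; genes with no
#' annotated site are absent.
#'
#' @param site_results Tibble with `site_id`, `dmp`.
#' @param annotation Probe annotation with `gene_symbols`.
#' @return Tibble: `gene`, `has_dmp`, `n_probes`.
#' @export
gene_level_table <- function(site_results, annotation) {
  d <- dplyr::inner_join(site_results |> select("site_id", "dmp"),
                         annotation |> select("site_id", "gene_symbols"),
                         by = "site_id") |>
    filter(nzchar(.data$gene_symbols)) |>
    tidyr::separate_rows("gene_symbols", sep = ";") |>
    filter(nzchar(.data$gene_symbols)) |>
    dplyr::distinct(.data$site_id, .data$gene_symbols, .keep_all = TRUE)
  d |>
    group_by(gene = .data$gene_symbols) |>
    summarise(has_dmp = any(.data$dmp), n_probes = dplyr::n(), .groups = "drop") |>
    arrange(.data$gene)
}

#' Gene-set enrichment controlling for gene size
#'
#' Logistic regression of gene-level DMP status on gene-set membership
#' with the number of annotated sites per gene as a covariate, so large
#' genes (which are more likely to contain a DMP by chance) do not
#' inflate the enrichment. The background is every gene in the table.
#'
#' @param gene_table From [gene_level_table()].
#' @param gene_set Character vector of gene symbols.
#' @param set_name Label for the output row.
#' @return One-row tibble: `category`, `n_set_genes` (in background),
#'   `effect` (log-odds), `odds_ratio`, `se`, `p`.
#' @export
geneset_enrichment <- function(gene_table, gene_set, set_name = "set") {
  in_set <- gene_table$gene %in% toupper(gene_set) |
    gene_table$gene %in% gene_set
  if (!any(in_set)) mt_abort("gene set '%s' has no overlap with the gene table", set_name)
  df <- data.frame(has_dmp = as.numeric(gene_table$has_dmp),
                   in_set = as.numeric(in_set),
                   n_probes = gene_table$n_probes)
  fit <- suppressWarnings(glm(has_dmp ~ in_set + n_probes,
                              data = df, family = binomial()))
  sm <- summary(fit)$coefficients
  tibble(category = set_name, n_set_genes = sum(in_set),
         n_dmp_set_genes = sum(in_set & gene_table$has_dmp),
         effect = sm["in_set", "Estimate"],
         odds_ratio = exp(sm["in_set", "Estimate"]),
         se = sm["in_set", "Std. Error"],
         p = sm["in_set", "Pr(>|z|)"])
}

#' Tiered gene-set enrichment over significance bins
#'
#' Ranks DMPs from most to least significant and repeats the gene-set
#' enrichment on increasing top-k bins. DMPs outside the current bin are
#' excluded from the analysis entirely (their sites are dropped before
#' the gene table is built), so the non-DMP background stays identical
#' across bins.
#'
#' @param site_results Tibble with `site_id`, `p`, `log10_p`, `dmp`.
#' @param annotation Probe annotation.
#' @param gene_set Character vector of gene symbols.
#' @param bin_sizes Integer vector of top-k bin sizes; values above the
#'   DMP count are clamped with a warning.
#' @param set_name Label.
#' @return Tibble: one [geneset_enrichment()] row per bin with
#'   `bin_size`.
#' @export
tiered_enrichment <- function(site_results, annotation, gene_set,
                              bin_sizes, set_name = "set") {
  dmps <- site_results |> filter(.data$dmp) |> arrange(.data$log10_p)
  n_dmp <- nrow(dmps)
  if (!n_dmp) mt_abort("no DMPs to bin")
  if (any(bin_sizes > n_dmp)) {
    mt_warn("bin size exceeding %d DMPs clamped", n_dmp)
    bin_sizes <- pmin(bin_sizes, n_dmp)
  }
  rows <- lapply(unique(bin_sizes), function(k) {
    top <- dmps$site_id[seq_len(k)]
    drop <- setdiff(dmps$site_id, top)
    sub <- site_results |> filter(!(.data$site_id %in% drop))
    gt <- gene_level_table(sub, annotation)
    res <- geneset_enrichment(gt, gene_set, set_name)
    dplyr::bind_cols(tibble(bin_size = k), res)
  })
  bind_rows(rows)
}
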