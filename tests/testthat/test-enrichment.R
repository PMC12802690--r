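# site_results + annotation fixture with controllable DMP/category link
make_enrich_fixture <- function(n = 1100, n_dmp_in = 30, n_in = 100,
                                n_dmp_out = 100) {
  tibble_res <- tibble::tibble(
    site_id = sprintf("cg%05d", seq_len(n)),
    effect = rnorm(n), se = 0.1, t = 1, p = runif(n), log10_p = log10(runif(n)),
    df = 20L, n_used = 24L, direction = "hyper",
    dmp = c(rep(TRUE, n_dmp_in), rep(FALSE, n_in - n_dmp_in),
            rep(TRUE, n_dmp_out), rep(FALSE, n - n_in - n_dmp_out)))
  ann <- tibble::tibble(
    site_id = tibble_res$site_id, chrom = "chr1",
    position = seq_len(n) * 1000,
    gene_symbols = "", probe_type = "cg",
    cgi_class = c(rep("island", n_in), rep("open_sea", n - n_in)),
    genic_class = "body")
  list(results = tibble_res, annotation = ann)
}

test_that("feature enrichment matches the 2x2 oracle", {
  fx <- make_enrich_fixture(n = 1100, n_dmp_in = 30, n_in = 100, n_dmp_out = 100)
  res <- feature_enrichment(fx$results, fx$annotation, "cgi_class")
  isl <- res[res$category == "island", ]
  # table (30, 70, 100, 900): log OR = ln(3.857)
  expect_equal(isl$effect, log((30 * 900) / (70 * 100)), tolerance = 1e-10)
  expect_equal(isl$odds_ratio, 30 * 900 / (70 * 100), tolerance = 1e-10)
  # chi-squared equals the textbook statistic
  tab <- matrix(c(30, 70, 100, 900), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(isl$chisq, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_equal(exp(isl$effect), isl$odds_ratio, tolerance = 1e-12)

  # a zero cell stays finite through the Haldane correction
  fx0 <- make_enrich_fixture(n = 500, n_dmp_in = 0, n_in = 50, n_dmp_out = 50)
  res0 <- feature_enrichment(fx0$results, fx0$annotation, "cgi_class")
  expect_true(all(is.finite(res0$effect)))
})

test_that("feature enrichment is null when DMP status ignores the category", {
  set.seed(31)
  n <- 4000
  fx <- make_enrich_fixture(n = n)
  fx$results$dmp <- runif(n) < 0.1
  res <- feature_enrichment(fx$results, fx$annotation, "cgi_class")
  expect_true(all(abs(res$effect) < 3 * res$se))
})

test_that("per-feature direction test departs from the genome-wide proportion", {
  set.seed(32)
  n <- 2000
  res <- tibble::tibble(
    site_id = sprintf("cg%05d", 1:n),
    effect = c(rep(1, 870), rep(-1, 130), ifelse(runif(n - 1000) < 0.435, 1, -1)),
    dmp = TRUE)
  ann <- tibble::tibble(site_id = res$site_id, chrom = "chr1",
                        position = 1:n * 1000, gene_symbols = "",
                        cgi_class = c(rep("island", 1000), rep("open_sea", n - 1000)),
                        genic_class = "body", probe_type = "cg")
  out <- direction_by_feature(res, ann, "cgi_class", p0 = 0.435)
  isl <- out[out$category == "island", ]
  expect_equal(isl$n_success, 870)
  # matches the exact enumeration oracle in log space
  expect_equal(isl$log10_p, log10(binom_tail_enum(870, 1000, 0.435)),
               tolerance = 1e-6)
  expect_lt(isl$p_corrected, 1e-100)

  # a category at the null proportion is unremarkable
  sea <- out[out$category == "open_sea", ]
  expect_gt(sea$p_one_tailed, 0.05)
})

test_that("peak enrichment recovers a planted log-odds in a joint model", {
  sim <- simulate_dataset(n_sites = 3000, n_samples = 20,
                          class_mix = c(0.5, 0.5, 0), seed = 33)
  ann <- simulate_annotation(sim$truth, n_cell_types = 3,
                             enrichment_factor = exp(1.27), seed = 33)
  res <- tibble::tibble(site_id = sim$truth$site_id, dmp = sim$truth$is_dmp)
  pe <- peak_enrichment(res, ann$annotation, ann$peaks)
  expect_equal(nrow(pe), 3)
  for (i in 1:3) {
    expect_lt(abs(pe$effect[i] - 1.27), 2.5 * pe$se[i])
    expect_equal(exp(pe$effect[i]), pe$odds_ratio[i], tolerance = 1e-12)
  }
  # the paper-style printed pair
  expect_equal(signif(exp(1.27), 3), 3.56)

  # membership independent of DMP status: effects near zero
  ann0 <- simulate_annotation(sim$truth, n_cell_types = 2,
                              enrichment_factor = 1, seed = 34)
  pe0 <- peak_enrichment(res, ann0$annotation, ann0$peaks)
  expect_true(all(abs(pe0$effect) < 3 * pe0$se))

  # duplicated peak sets are unidentifiable
  dup <- dplyr::mutate(ann$peaks[ann$peaks$cell_type == "celltype1", ],
                       cell_type = "copycat")
  expect_error(peak_enrichment(res, ann$annotation,
                               dplyr::bind_rows(ann$peaks, dup)),
               "collinear")
})

test_that("gene-level table counts probes and propagates multi-gene probes", {
  res <- tibble::tibble(site_id = c("cg1", "cg2", "cg3", "cg4"),
                        dmp = c(TRUE, FALSE, FALSE, FALSE))
  ann <- tibble::tibble(site_id = res$site_id, chrom = "chr1",
                        position = 1:4 * 100,
                        gene_symbols = c("A", "A;B", "B", ""),
                        cgi_class = "island", genic_class = "body",
                        probe_type = "cg")
  gt <- gene_level_table(res, ann)
  expect_equal(gt$gene, c("A", "B"))
  expect_equal(gt$n_probes, c(2L, 2L))
  expect_equal(gt$has_dmp, c(TRUE, FALSE))
})

test_that("gene-set enrichment controls for gene size and recovers planted odds", {
  set.seed(35)
  n_genes <- 400
  genes <- sprintf("G%03d", 1:n_genes)
  n_probes <- sample(1:50, n_genes, replace = TRUE)
  in_set <- runif(n_genes) < 0.15
  # planted log-odds of 2 for set genes, plus a gene-size effect
  lin <- -2 + 0.05 * n_probes + 2 * in_set
  has_dmp <- runif(n_genes) < plogis(lin)
  gt <- tibble::tibble(gene = genes, has_dmp = has_dmp, n_probes = n_probes)
  res <- geneset_enrichment(gt, genes[in_set], set_name = "planted")
  expect_lt(abs(res$effect - 2), 2.5 * res$se)

  # independence given gene size: null effect
  has0 <- runif(n_genes) < plogis(-2 + 0.05 * n_probes)
  gt0 <- tibble::tibble(gene = genes, has_dmp = has0, n_probes = n_probes)
  res0 <- geneset_enrichment(gt0, genes[in_set], set_name = "null")
  expect_lt(abs(res0$effect), 3 * res0$se)

  expect_error(geneset_enrichment(gt, c("NOPE1", "NOPE2")), "no overlap")
})

test_that("tiered enrichment keeps a consistent background and clamps bins", {
  set.seed(36)
  n <- 600
  res <- tibble::tibble(
    site_id = sprintf("cg%05d", 1:n),
    effect = rnorm(n), se = 0.1, t = 0,
    p = sort(runif(n)), df = 20L, n_used = 24L, direction = "hyper",
    dmp = c(rep(TRUE, 100), rep(FALSE, n - 100)))
  res$log10_p <- log10(res$p)
  ann <- tibble::tibble(site_id = res$site_id, chrom = "chr1",
                        position = 1:n * 1000,
                        gene_symbols = sprintf("G%03d", rep(1:200, each = 3)),
                        cgi_class = "island", genic_class = "body",
                        probe_type = "cg")
  gs <- sprintf("G%03d", 1:30)
  full <- tiered_enrichment(res, ann, gs, bin_sizes = 100)
  plain <- geneset_enrichment(gene_level_table(res, ann), gs)
  expect_equal(full$effect, plain$effect, tolerance = 1e-12)

  expect_warning(tiered_enrichment(res, ann, gs, bin_sizes = 500), "clamped")

  tiers <- tiered_enrichment(res, ann, gs, bin_sizes = c(25, 50, 100))
  expect_equal(tiers$bin_size, c(25, 50, 100))
})
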