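#' Simulate a developmental methylation dataset with known truth
#'
#' Generates a beta matrix (sites x samples), a sample sheet, and a truth
#' table emulating array methylation across prenatal cortex development.
#' Each site follows one of three trajectory classes against age:
#' `constant` (flat at its baseline), `linear` (baseline plus a slope in
#' percentage points per week, anchored at the lower end of the age
#' range), or `nonlinear` (sigmoid, gaussian bump, or sine shapes).
#' Observed values are the mean curve plus sex/batch offsets plus additive
#' Gaussian noise, clipped to \[0.001, 0.999\].
#'
#' Class counts are allocated deterministically by largest remainder, so
#' `n_sites = 1000` with `class_mix = c(0.8, 0.1, 0.1)` always yields
#' exactly 800/100/100 sites. Ages are uniform over `age_range`, sex is
#' Bernoulli(0.5), and samples are split evenly across `n_batches`.
#'
#' @param n_sites,n_samples Dataset dimensions (`n_samples >= 10`).
#' @param age_range Age span in post-conception weeks; defaults to the
#'   6-23 pcw window of early/mid-gestation cortex.
#' @param class_mix Proportions of (constant, linear, nonlinear) sites;
#'   must sum to 1 within 1e-9.
#' @param effect_grid List of effect-size settings: `slope_range`
#'   (|slope| in pp/week for linear sites), `amplitude_range` (proportion
#'   scale, nonlinear), `sigmoid_width`, `bump_width_range`,
#'   `sine_period_range` (pcw), and `shapes` to draw from.
#' @param noise_sd Gaussian noise SD on the proportion scale.
#' @param sex_effect Offset added for female samples (proportion; default
#'   0.005, i.e. 0.5 percentage points).
#' @param batch_effect Offset added per non-reference batch (default
#'   0.01, i.e. 1 percentage point).
#' @param n_batches Number of experimental batches (2-4).
#' @param dmp_min_slope Design-time |slope| (pp/week) above which a linear
#'   site is marked a true DMP in the truth table.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list with `beta` (matrix), `sheet` (tibble), `truth`
#'   (tibble: site_id, class, slope, shape, shape parameters, is_dmp).
#' @export
#' @examples
#' sim <- simulate_dataset(n_sites = 50, n_samples = 20, seed = 1)
#' dim(sim$beta)
simulate_dataset <- function(n_sites, n_samples,
                             age_range = c(6, 23),
                             class_mix = c(constant = 0.8, linear = 0.1, nonlinear = 0.1),
                             effect_grid = list(),
                             noise_sd = 0.05,
                             sex_effect = 0.005,
                             batch_effect = 0.01,
                             n_batches = 3,
                             dmp_min_slope = 0.5,
                             seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9) mt_abort("class_mix must sum to 1")
  if (n_samples < 10) mt_abort("n_samples must be >= 10")
  if (noise_sd < 0) mt_abort("noise_sd must be >= 0")
  if (n_batches < 2 || n_batches > 4) mt_abort("n_batches must be in 2..4")
  eg <- utils::modifyList(list(
    slope_range = c(0.5, 2),
    amplitude_range = c(0.1, 0.3),
    sigmoid_width = 3,
    bump_width_range = c(2, 5),
    sine_period_range = c(10, 30),
    shapes = c("sigmoid", "gaussian_bump", "sine")
  ), effect_grid)

  set.seed(seed)
  # largest-remainder allocation of class counts
  raw <- n_sites * class_mix / sum(class_mix)
  cnt <- floor(raw)
  rem <- n_sites - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  classes <- rep(c("constant", "linear", "nonlinear"), times = cnt)

  site_ids <- sprintf("cg%07d", seq_len(n_sites))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  age <- runif(n_samples, age_range[1], age_range[2])
  sex <- ifelse(rbinom(n_samples, 1, 0.5) == 1, "F", "M")
  batch <- paste0("B", rep_len(seq_len(n_batches), n_samples))

  baseline <- runif(n_sites, 0.15, 0.85)
  slope <- rep(0, n_sites)
  is_lin <- classes == "linear"
  slope[is_lin] <- sample(c(-1, 1), sum(is_lin), replace = TRUE) *
    runif(sum(is_lin), eg$slope_range[1], eg$slope_range[2])
  shape <- rep(NA_character_, n_sites)
  is_nl <- classes == "nonlinear"
  shape[is_nl] <- sample(eg$shapes, sum(is_nl), replace = TRUE)
  amplitude <- ifelse(is_nl,
                      sample(c(-1, 1), n_sites, replace = TRUE) *
                        runif(n_sites, eg$amplitude_range[1], eg$amplitude_range[2]),
                      NA_real_)
  inflection <- ifelse(is_nl, runif(n_sites, age_range[1] + 2, age_range[2] - 2), NA_real_)
  width <- rep(NA_real_, n_sites)
  width[is_nl & shape == "sigmoid"] <- eg$sigmoid_width
  nb <- which(is_nl & shape == "gaussian_bump")
  width[nb] <- runif(length(nb), eg$bump_width_range[1], eg$bump_width_range[2])
  ns <- which(is_nl & shape == "sine")
  width[ns] <- runif(length(ns), eg$sine_period_range[1], eg$sine_period_range[2])

  mu <- matrix(0, n_sites, n_samples)
  for (i in seq_len(n_sites)) {
    mu[i, ] <- trajectory_mean(age, classes[i], baseline[i], slope[i],
                               shape[i], inflection[i], width[i], amplitude[i],
                               age0 = age_range[1])
  }
  off <- matrix(rep(ifelse(sex == "F", sex_effect, 0) +
                      ifelse(batch == "B1", 0, batch_effect),
                    each = n_sites), n_sites, n_samples)
  eps <- if (noise_sd > 0) {
    matrix(rnorm(n_sites * n_samples, 0, noise_sd), n_sites, n_samples)
  } else 0
  beta <- clip01(mu + off + eps)
  dimnames(beta) <- list(site_ids, sample_ids)

  sheet <- tibble(
    sample_id = sample_ids, age_value = age, age_unit = "pcw",
    sex = sex, batch = batch, donor_id = paste0("D", seq_len(n_samples)),
    fraction = "bulk", stage = "prenatal"
  )
  truth <- tibble(
    site_id = site_ids, class = classes, baseline = baseline,
    slope = slope, shape = shape, inflection = inflection,
    width = width, amplitude = amplitude, noise_sd = noise_sd,
    is_dmp = classes == "linear" & abs(slope) >= dmp_min_slope
  )
  list(beta = beta, sheet = sheet, truth = truth)
}

# Mean trajectory of one site over age (proportion scale). slope is in
# percentage points per week; baseline anchors the curve at age0.
trajectory_mean <- function(age, class, baseline, slope, shape,
                            inflection, width, amplitude, age0 = 6) {
  switch(class,
    constant = rep(baseline, length(age)),
    linear = baseline + (slope / 100) * (age - age0),
    nonlinear = switch(shape,
      sigmoid = baseline + amplitude * plogis((age - inflection) / width),
      gaussian_bump = baseline + amplitude * exp(-(age - inflection)^2 / (2 * width^2)),
      sine = baseline + amplitude * sin(2 * pi * (age - age0) / width),
      mt_abort("unknown nonlinear shape '%s'", shape)
    ),
    mt_abort("unknown trajectory class '%s'", class)
  )
}

#' Simulate annotation, open-chromatin peaks and gene sets for a truth table
#'
#' Places simulated sites on two synthetic chromosomes with a mixture of
#' clustered runs (consecutive gaps below 500 bp, so region candidates
#' exist) and isolated sites, assigns CpG-island and genic feature
#' classes, links sites to genes, and plants known enrichment: for
#' true-DMP sites, the odds of falling inside each cell type's
#' open-chromatin peak set — and the odds that their genes belong to each
#' gene set — are multiplied by `enrichment_factor` (so the planted
#' log-odds is `log(enrichment_factor)`; a factor of 1 plants the null).
#'
#' @param truth Truth table from [simulate_dataset()].
#' @param n_genes Size of the synthetic gene pool.
#' @param n_cell_types Number of peak sets.
#' @param geneset_sizes Integer vector of gene-set sizes.
#' @param enrichment_factor Multiplicative odds factor (> 0) applied to
#'   true-DMP sites/genes.
#' @param base_peak_rate Baseline probability a non-DMP site lies in a
#'   given cell type's peaks.
#' @param cluster_frac Fraction of sites placed in clustered runs.
#' @param seed Integer seed.
#' @return A list: `annotation` (tibble), `peaks` (tibble:
#'   cell_type/chrom/start/end), `gene_sets` (named list), and `truth`
#'   augmented with per-cell-type `in_peak_*` flags.
#' @export
simulate_annotation <- function(truth, n_genes = 200, n_cell_types = 3,
                                geneset_sizes = c(30, 30),
                                enrichment_factor = 1,
                                base_peak_rate = 0.08,
                                cluster_frac = 0.4,
                                seed = 1L) {
  if (enrichment_factor <= 0) mt_abort("enrichment_factor must be > 0")
  set.seed(child_seed(seed, 11L))
  n <- nrow(truth)
  chrom <- rep(c("chrS1", "chrS2"), length.out = n)
  position <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    pos <- numeric(m)
    cur <- 10000
    i <- 1
    while (i <= m) {
      if (runif(1) < cluster_frac && i + 2 <= m) {
        run <- min(sample(3:6, 1), m - i + 1)  # clustered run, gaps < 500 bp
        gaps <- sample(50:450, run - 1, replace = TRUE)
        pos[i:(i + run - 1)] <- cur + c(0, cumsum(gaps))
        cur <- pos[i + run - 1] + sample(5000:50000, 1)
        i <- i + run
      } else {
        pos[i] <- cur
        cur <- cur + sample(5000:50000, 1)
        i <- i + 1
      }
    }
    position[idx] <- as.integer(pos)
  }

  cgi_levels <- c("island", "north_shore", "south_shore",
                  "north_shelf", "south_shelf", "open_sea")
  cgi_class <- sample(cgi_levels, n, replace = TRUE,
                      prob = c(0.18, 0.08, 0.08, 0.04, 0.04, 0.58))
  genic_levels <- c("TSS1500", "TSS200", "5'UTR", "body", "3'UTR", "intergenic")
  genic_class <- sample(genic_levels, n, replace = TRUE,
                        prob = c(0.1, 0.07, 0.08, 0.4, 0.05, 0.3))

  gene_pool <- sprintf("GENE%04d", seq_len(n_genes))
  n_gene_links <- sample(0:2, n, replace = TRUE, prob = c(0.3, 0.6, 0.1))
  gene_symbols <- vapply(n_gene_links, function(k) {
    if (k == 0) "" else paste(sample(gene_pool, k), collapse = ";")
  }, "")

  annotation <- tibble(
    site_id = truth$site_id, chrom = chrom, position = position,
    gene_symbols = gene_symbols, cgi_class = cgi_class,
    genic_class = genic_class, probe_type = "cg"
  )

  # peak membership: logit(base rate) + log(enrichment_factor) for true DMPs
  base_logit <- log(base_peak_rate / (1 - base_peak_rate))
  peaks <- list()
  for (ct in seq_len(n_cell_types)) {
    lab <- paste0("celltype", ct)
    pr <- plogis(base_logit + ifelse(truth$is_dmp, log(enrichment_factor), 0))
    member <- rbinom(n, 1, pr) == 1
    truth[[paste0("in_peak_", lab)]] <- member
    if (any(member)) {
      peaks[[lab]] <- tibble(
        cell_type = lab, chrom = chrom[member],
        start = position[member] - 1L - 20L,
        end = position[member] - 1L + 21L
      ) |> arrange(.data$chrom, .data$start)
    } else {
      peaks[[lab]] <- tibble(cell_type = character(), chrom = character(),
                             start = integer(), end = integer())
    }
  }

  # gene sets enriched for genes carrying true-DMP sites
  gene_hits <- unique(unlist(strsplit(gene_symbols[truth$is_dmp], ";", fixed = TRUE)))
  gene_hits <- gene_hits[nzchar(gene_hits)]
  w <- ifelse(gene_pool %in% gene_hits, enrichment_factor, 1)
  gene_sets <- list()
  for (j in seq_along(geneset_sizes)) {
    k <- min(geneset_sizes[j], n_genes)
    gene_sets[[paste0("SET", j)]] <- sample(gene_pool, k, prob = w)
  }
  list(annotation = annotation, peaks = bind_rows(peaks),
       gene_sets = gene_sets, truth = truth)
}

#' Simulate a purified reference panel for deconvolution
#'
#' Builds per-cell-type mean methylation profiles that differ at a
#' configurable number of discriminating sites, then draws purified
#' samples around them with Gaussian noise.
#'
#' @param n_sites Number of array sites.
#' @param cell_types Character vector of cell-type labels.
#' @param n_per_type Purified samples per cell type.
#' @param n_distinct Number of sites at which each cell type departs from
#'   the shared baseline profile.
#' @param delta Size of the departure (proportion scale).
#' @param noise_sd Noise SD for purified samples.
#' @param seed Integer seed.
#' @return List: `beta` (sites x samples), `cell_labels`, `profiles`
#'   (sites x cell types matrix of true means).
#' @export
simulate_reference_panel <- function(n_sites = 500,
                                     cell_types = c("ESC", "NPC", "NeuN+", "NeuN-"),
                                     n_per_type = 5, n_distinct = 60,
                                     delta = 0.35, noise_sd = 0.02, seed = 1L) {
  set.seed(child_seed(seed, 23L))
  k <- length(cell_types)
  base <- runif(n_sites, 0.2, 0.8)
  profiles <- matrix(base, n_sites, k,
                     dimnames = list(sprintf("cg%07d", seq_len(n_sites)), cell_types))
  for (j in seq_len(k)) {
    idx <- sample.int(n_sites, n_distinct)
    profiles[idx, j] <- clip01(profiles[idx, j] +
                                 sample(c(-delta, delta), n_distinct, replace = TRUE))
  }
  labels <- rep(cell_types, each = n_per_type)
  beta <- profiles[, rep(seq_len(k), each = n_per_type)] +
    matrix(rnorm(n_sites * k * n_per_type, 0, noise_sd), n_sites)
  beta <- clip01(beta)
  colnames(beta) <- sprintf("%s_%d", labels, sequence(rep(n_per_type, k)))
  list(beta = beta, cell_labels = labels, profiles = profiles)
}

#' Simulate bulk mixtures from reference profiles
#'
#' Each bulk sample is a Dirichlet-weighted combination of the reference
#' cell-type profiles plus additive Gaussian noise, clipped to
#' \[0.001, 0.999\].
#'
#' @param profiles Sites x cell-types matrix of reference methylation
#'   means in \[0,1\].
#' @param n_mixtures Number of bulk samples.
#' @param dirichlet_alpha Dirichlet concentration (scalar or per cell
#'   type).
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @return List: `beta` (sites x mixtures), `proportions` (mixtures x
#'   cell types, rows sum to 1).
#' @export
simulate_mixtures <- function(profiles, n_mixtures, dirichlet_alpha = 1,
                              noise_sd = 0.01, seed = 1L) {
  if (any(profiles < 0 | profiles > 1)) mt_abort("reference profiles must lie in [0,1]")
  set.seed(child_seed(seed, 37L))
  k <- ncol(profiles)
  alpha <- rep_len(dirichlet_alpha, k)
  w <- rdirichlet(n_mixtures, alpha)
  colnames(w) <- colnames(profiles)
  rownames(w) <- sprintf("mix%03d", seq_len(n_mixtures))
  beta <- profiles %*% t(w)
  if (noise_sd > 0) {
    beta <- beta + matrix(rnorm(length(beta), 0, noise_sd), nrow(beta))
  }
  beta <- clip01(beta)
  dimnames(beta) <- list(rownames(profiles), rownames(w))
  list(beta = beta, proportions = w)
}
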