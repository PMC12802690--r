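---
title: "Modelling DNA methylation trajectories across cortical development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA methylation trajectories across cortical development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methtraj)
```

# Scope and model overview

`methtraj` analyses array-style DNA methylation data (beta values:
proportions in [0, 1]) measured across developmental time, with the
prenatal human cortex (ages in post-conception weeks, pcw) as the
motivating system. The pipeline has six analytical stages, each usable on
its own:

1. **Per-site linear models** of methylation against age, adjusted for
   sex and batch, calling developmentally differentially methylated
   positions (dDMPs) at the experiment-wide array threshold
   $p < 9\times10^{-8}$.
2. **Region calling**: chaining dDMPs within 500 bp of their neighbours
   into candidate regions and combining their effects with a
   correlation-adjusted inverse-variance meta-analysis.
3. **Gaussian-process trajectory classification** of each site as
   constant, linear, or nonlinear (Matérn 5/2 kernel), by marginal
   likelihood, with a log-likelihood-ratio and timescale refinement.
4. **Co-methylation modules** over nonlinear sites: a signed weighted
   network, topological overlap, hierarchical module detection,
   eigengenes and hub sites.
5. **Enrichment statistics**: chi-squared feature/chromosome tests,
   per-feature direction binomials, a joint logistic model for
   open-chromatin peak enrichment, and gene-set enrichment controlling
   for gene size, including the tiered-bin variant.
6. **Cell-type deconvolution** of bulk profiles against a purified
   reference panel by non-negative least squares, scored by a
   root-mean-square reconstruction error (a CETYGO-style score).

A synthetic-data generator produces beta matrices, sample sheets,
annotations, peak sets, gene sets and cell mixtures with known ground
truth, so every stage is testable end to end without any external data.

# The per-site linear model

For site $j$ with methylation proportions $y_{ij}$ over samples $i$:

$$y_{ij} = \beta_0 + \beta_a \, \text{age}_i + \boldsymbol\gamma^\top
\mathbf{c}_i + \varepsilon_{ij}$$

fitted by ordinary least squares per site with complete-case exclusion of
missing values. The age coefficient is reported in percentage points per
week ($100\,\beta_a$), with a two-sided $p$ from the $t$ distribution at
the residual degrees of freedom. When no values are missing all sites
share one design matrix and the scan is computed by a single matrix
product, so a permuted-age null with a thousand sites runs in well under
a second.

Extreme p-values are carried in $\log_{10}$ space throughout (`log10_p`);
the `p` column underflows to zero below roughly $10^{-308}$ while
`log10_p` stays exact. Printed output formats values below $10^{-320}$ as
`<1e-320`.

The direction test is the exact one-tailed binomial tail
$P(X \ge k \mid n, p_0)$ computed in log space via `pbinom(log.p =
TRUE)`. For the genome-wide test $p_0 = 0.5$; for per-feature direction
tests $p_0$ defaults to the hypermethylated proportion across all dDMPs,
with the alternative chosen in the direction of departure. An `p0`
argument exposes the alternative convention (all-array proportion) should
a user prefer it.

Mixed-effects cell-type models (`fit_site_mixed()`) use a random donor
intercept fitted by REML for estimates; significance of the cell-type
term comes from a likelihood-ratio test between nested maximum-likelihood
refits. When the fitted donor variance is singular the site falls back to
a fixed-effects fit and is flagged — with zero donor variance the two
coincide. The interaction model (`fit_interaction()`) is fixed-effects
only, matching the bulk model design; stratified per-fraction slopes are
re-estimated on the same samples so they are directly comparable.

# Region statistic

Candidate regions are maximal chains of dDMPs in which each consecutive
pair lies within 500 bp (the gap bound applies between neighbours, so a
chain may span more). Chains need at least three dDMPs. For a candidate
with effects $\mathbf b$, standard errors $\mathbf s$ and residual
correlation $R$ (Pearson correlation of the sites' OLS residuals after
covariate adjustment), the combined statistic is

$$\Sigma = \operatorname{diag}(\mathbf s)\, R \,
\operatorname{diag}(\mathbf s), \qquad
B = \frac{\mathbf 1^\top \Sigma^{-1}\mathbf b}
          {\mathbf 1^\top \Sigma^{-1}\mathbf 1}, \qquad
\operatorname{se}(B) = (\mathbf 1^\top \Sigma^{-1}\mathbf 1)^{-1/2},$$

with a two-sided normal $p$ on $z = B/\operatorname{se}(B)$ and
Bonferroni correction over candidates. With $R = I$ this is exactly
classical fixed-effect inverse-variance meta-analysis; a ridge
($10^{-6}$ of the diagonal) is added only if the Cholesky factorisation
fails, so the identity case is untouched numerically. Direction
consistency within a region is not required; mixed-sign regions are kept
and flagged. Sub-region enumeration (scanning all windows, as the full
dmrff algorithm does) is out of scope; candidates are the maximal chains
only.

# Gaussian-process trajectory classification

Each site's centred values are modelled as a zero-mean GP over age with
one of three kernels, every one containing a bias (constant offset) and
white-noise term:

* constant: $K = \sigma_b^2 J + \sigma_n^2 I$
* linear: adds $\sigma_v^2\, x x^\top$ (uncentred $x$ in raw pcw; with
  $y$ centred this is a Bayesian straight line with free intercept)
* nonlinear: adds the Matérn 5/2 covariance
  $\sigma_f^2\,(1 + \sqrt5 r/\ell + 5r^2/(3\ell^2))\,e^{-\sqrt5 r/\ell}$
  with lengthscale ("timescale") $\ell$ in pcw.

Raw pcw ages are used deliberately so $\ell$ is directly interpretable;
the period of one full oscillation is $2\pi\sqrt{3/5}\,\ell \approx
4.87\,\ell$, i.e. a timescale of 1 oscillates roughly every 5 pcw.

Hyperparameters are optimised on the log scale by L-BFGS-B with analytic
gradients, 5 restarts (one data-driven start plus seeded log-uniform
draws), variance bounds $[10^{-12}, 10]$ and $\ell \in [0.5, 200]$ pcw.
The variance floor sits far below any data scale on purpose: with
uncentred ages up to ~25 pcw, a floor of $10^{-8}$ on $\sigma_v^2$ still
contributes visible covariance and breaks the nested ordering
$L_{\text{lin}}, L_{\text{nl}} \ge L_{\text{const}}$. The linear and
Matérn fits are additionally warm-started from the constant optimum,
which keeps the nested ordering clean to optimiser tolerance (observed
violations are below $10^{-4}$ log units). Cholesky failures walk a
jitter ladder from $10^{-10}$ to $10^{-6}$ of the mean diagonal.

**Classification and the LLR margin.** The `class` column is the argmax
of the three optimised log marginal likelihoods, with ties (differences
under $10^{-6}$) broken towards the simpler model. Because the constant
model is nested in the Matérn model, type-II maximum likelihood lets the
richer kernel chase chance autocorrelation in pure noise: on simulated
constant sites ($n = 90$, noise sd 0.03) the Matérn optimum genuinely
exceeds the constant optimum by up to ~1.5 log units in roughly a third
of sites — we confirmed the same behaviour with an independent GP
implementation, so it is a property of the procedure, not of our
optimiser. The argmax column therefore over-calls nonlinear, which is
why the pipeline refines nonlinear calls by the log-likelihood ratio
against *both* simpler kernels. The `class_refined` column applies that
margin at the classification stage: a site is called nonlinear only when
$\min(L_{\text{nl}} - L_{\text{const}}, L_{\text{nl}} - L_{\text{lin}})
\ge 2$, otherwise it falls back to the better of constant and linear.
On a 300-site benchmark (100 sites per class: constant; linear at
1 pp/week; sigmoid of amplitude 0.2 and width 3 pcw; noise sd 0.03,
$n = 90$) the refined classification is the accuracy we quote; the raw
argmax column is retained because the downstream high-confidence
refinement expects it.

The **high-confidence** set additionally requires the timescale floor
$\ell \ge 10$ pcw (both bounds inclusive), excluding implausibly fast
oscillations. Note that a sigmoid of width 3 pcw typically fits
$\ell < 10$: the high-confidence set targets slow, biologically
meaningful nonlinearity and is deliberately stricter than the
classification itself.

# Co-methylation modules

The signed adjacency $a_{ij} = ((1 + \operatorname{cor}(x_i, x_j))/2)^{12}$
(Pearson, proportion scale; soft threshold 12, the standard signed-network
recommendation at this sample size) is converted to topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

and modules come from average-linkage clustering on $1-\mathrm{TOM}$
with a **static** cut (default height 0.995) — a deliberate
simplification of dynamic tree cutting; the cut height and minimum
module size (30) are exposed as parameters rather than guessed, since
module structure is data-dependent anyway. Clusters below the minimum
size become `"unassigned"` (the grey-equivalent) and are excluded from
eigengene and hub computation. Eigengenes are the first principal
component of the module's standardised site-by-sample matrix, oriented
so the mean member kME is positive; hub sites are the members most
correlated with the eigengene. `pca_project()` maps one cohort into
another's PC space using the reference cohort's centering, scaling and
loadings only.

# Enrichment statistics

Feature/chromosome enrichment uses the chi-squared test without
continuity correction on each category's 2×2 table, reporting the log
odds ratio (Haldane +0.5 on zero cells) — `exp(effect)` always equals
the reported odds ratio. Peak enrichment is a **single joint** logistic
regression of DMP status on all cell-type membership indicators, so each
coefficient is adjusted for all other cell types; perfectly collinear
peak sets are rejected by name, and complete separation falls back to a
Fisher exact p with an infinite-effect sentinel. Gene-set enrichment is
logistic regression of gene-level DMP status on set membership
controlling for the number of probes annotated to the gene; probes
annotated to several genes count for each. The tiered variant ranks
DMPs by significance and, for each top-$k$ bin, removes out-of-bin DMPs
from the analysis entirely so the non-DMP background is identical across
bins. "Corrected p" is Bonferroni throughout — conservative and
consistent with extreme reported values.

# Deconvolution

Reference probes are chosen per cell type by one-vs-rest Welch
t-statistics, taking the top 100 by $|t|$ regardless of sign (the
`"any"` selection mode); the exact ranking statistic of upstream
implementations is not documented, so the $|t|$ top-N convention is
declared explicitly rather than inferred. Proportions solve
$\min_{w \ge 0} \lVert y - Xw\rVert_2$ per sample (Lawson–Hanson NNLS)
with no sum-to-one constraint — $\sum w$ is reported as a diagnostic.
The reconstruction error $\sqrt{\text{mean}((y - Xw)^2)}$ is zero for
exact mixtures, tracks the noise floor on noisy ones, and rises when the
reference omits a cell type actually present.

# The synthetic-data generator

`simulate_dataset()` emulates the study conditions: ages uniform on
6–23 pcw (the early/mid-gestation window), sex Bernoulli(0.5), 2–4
batches, and per-site trajectories that are constant, linear (slopes of
0.5–2 pp/week by default, matching the magnitude of reported top
effects), or nonlinear (sigmoid, Gaussian bump, or sine with
configurable period so timescale recovery can be checked against the
analytic conversion). Noise is additive Gaussian on the proportion scale
with clipping to [0.001, 0.999] — chosen over a beta distribution
because it matches the linear-model assumptions of the analyses and
keeps oracle math exact; with zero noise every curve equals its
specification exactly. Sex and batch offsets default to 0.5 and 1
percentage points, realistic nuisance magnitudes. Class counts are
allocated by largest remainder, so mixtures are exact and deterministic.

`simulate_annotation()` places sites on two synthetic chromosomes as a
mixture of clustered runs (consecutive gaps of 50–450 bp, so region
candidates exist) and isolated sites, and plants known enrichment: the
odds of a true-DMP site falling in a peak set — and of its genes
belonging to a gene set — are multiplied by `enrichment_factor`, so the
planted log-odds is its log. `simulate_mixtures()` builds bulk samples
as Dirichlet-weighted combinations of reference profiles.

What the generator does **not** emulate: probe hybridisation artefacts,
SNP-affected probes, hydroxymethylation, beta-value heteroscedasticity
near the boundaries, or spatial correlation of noise along the genome.
Passing tests on synthetic data therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
artefact of real arrays.

# Numerical choices and problem sizes

* Extreme p-values: log-space throughout; displayed as `<1e-320` late.
* GP: analytic gradients; 5 restarts; jitter ladder
  $10^{-10}$–$10^{-6}$; tie window $10^{-6}$ towards simpler models;
  LLR margin 2 for the refined class.
* Region statistic: ridge applied only on Cholesky failure.
* NNLS tolerance: solver KKT conditions at $10^{-10}$.
* Default test-suite problem sizes are chosen to exercise each method at
  meaningful power while keeping the whole suite fast: the GP benchmark
  uses 300 sites at $n = 90$; the mixed-model null calibration 300
  sites; null-region family-wise error 200 replicates at 60 sites;
  deconvolution recovery 100 mixtures. These are the package's own
  choices of demonstration scale.

# Known limitations

* Static-height tree cut, not dynamic tree cut: module boundaries on
  real data will differ from a full WGCNA run.
* The region statistic evaluates maximal chains only, not all
  sub-regions.
* The GP stage assumes a centred zero-mean process; a free mean function
  would absorb slow drifts slightly differently.
* Deconvolution accuracy depends entirely on the reference panel; the
  generator's panels are idealised.
* The timescale-to-period conversion $2\pi\sqrt{3/5}\,\ell$ is the Rice
  mean-crossing period of a stationary GP sample path. For a
  *deterministic* sinusoid, maximum-likelihood Matérn fits settle on a
  lengthscale roughly twice the Rice-implied value (we confirmed the
  same lengthscales with an independent GP implementation), so
  converted periods for clean single tones run ~1.5–2× the planted
  period while still scaling linearly with it. Interpret periods as
  order-of-magnitude oscillation rates, not calibrated frequencies.
* The interaction model has no donor random intercept by default (a
  documented design choice; `fit_site_mixed()` covers the paired case).
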