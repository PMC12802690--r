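#' Run the developmental methylome pipeline
#'
#' Convenience wrapper chaining the standard stages on one dataset:
#' QC filtering ([qc_filter()]), the per-site linear scan
#' ([fit_dmps()]) with the genome-wide direction test, region calling
#' ([call_dmrs()]) when an annotation is supplied, and GP trajectory
#' classification ([classify_sites()]) on the QC-retained sites (capped
#' at `max_gp_sites`, most variable first, since GP fitting dominates
#' runtime). Deterministic given `seed`.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet.
#' @param annotation Optional probe annotation (enables DMR calling).
#' @param covariates Adjustment covariates for the linear models.
#' @param alpha dDMP threshold.
#' @param run_gp Run the GP classification stage.
#' @param max_gp_sites Cap on sites classified by GP.
#' @param seed Integer seed.
#' @return A list: `qc` (report), `dmps`, `direction`, `dmrs` (or
#'   NULL), `gp` (or NULL).
#' @export
run_pipeline <- function(beta, sheet, annotation = NULL,
                         covariates = c("sex", "batch"), alpha = 9e-8,
                         run_gp = TRUE, max_gp_sites = 200, seed = 1L) {
  qc <- qc_filter(beta)
  dmps <- fit_dmps(beta, sheet, covariates = covariates, alpha = alpha)
  dir_test <- if (any(dmps$dmp, na.rm = TRUE)) {
    direction_binomial(dmps$effect[which(dmps$dmp)], success = "hypo")
  } else NULL
  dmrs <- if (!is.null(annotation) && any(dmps$dmp, na.rm = TRUE)) {
    call_dmrs(dmps, beta, sheet, annotation, covariates = covariates)
  } else NULL
  gp <- NULL
  if (run_gp && nrow(qc$beta) > 0) {
    bg <- qc$beta
    if (nrow(bg) > max_gp_sites) {
      v <- apply(bg, 1, var, na.rm = TRUE)
      bg <- bg[order(-v)[seq_len(max_gp_sites)], , drop = FALSE]
    }
    gp <- classify_sites(bg, sheet, seed = seed)
  }
  list(qc = qc$report, dmps = dmps, direction = dir_test, dmrs = dmrs, gp = gp)
}
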