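#' Read a beta matrix from delimited text
#'
#' A beta matrix holds methylation proportions (beta values) in \[0,1\],
#' sites in rows and samples in columns. The file is tab-delimited with a
#' header row of sample identifiers and site identifiers in the first
#' column; missing values use the `NA` token.
#'
#' @param path Path to a TSV file.
#' @return A numeric matrix with unique site rownames and sample colnames.
#'   All non-missing values lie in \[0,1\].
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_beta_matrix(matrix(c(0.1, 0.9), 1, 2,
#'   dimnames = list("cg1", c("s1", "s2"))), tf)
#' read_beta_matrix(tf)
read_beta_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) mt_abort("beta matrix file '%s' needs site IDs plus >=1 sample column", path)
  site_ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col) & col != "NA")
      mt_abort("non-numeric value in column '%s', row '%s'",
               names(vals)[j], site_ids[bad[1]])
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- site_ids
  validate_beta_matrix(m)
}

#' Validate a beta matrix
#'
#' Checks unique site and sample identifiers and that all non-missing
#' values are within \[0,1\].
#'
#' @param beta Numeric matrix, sites x samples, with dimnames.
#' @return The matrix, invisibly validated (returned unchanged).
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) mt_abort("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    mt_abort("beta must carry site rownames and sample colnames")
  if (anyDuplicated(rownames(beta)))
    mt_abort("duplicate site IDs: %s", rownames(beta)[duplicated(rownames(beta))][1])
  if (anyDuplicated(colnames(beta)))
    mt_abort("duplicate sample IDs: %s", colnames(beta)[duplicated(colnames(beta))][1])
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    mt_abort("beta value out of [0,1] at site '%s', sample '%s'",
             rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]])
  beta
}

#' Write a beta matrix to delimited text
#'
#' Inverse of [read_beta_matrix()]; round-trips values losslessly at
#' double precision (values are written with 17 significant digits).
#'
#' @param beta Numeric matrix, sites x samples.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  df <- data.frame(site_id = rownames(beta),
                   format(beta, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample sheet
#'
#' The sample sheet carries per-sample covariates: `sample_id`,
#' `age_value`, `age_unit` (`"pcw"` for prenatal post-conception weeks or
#' `"years"`), `sex` (`"M"`/`"F"`), `batch`, `donor_id`, `fraction`
#' (e.g. `"bulk"`, `"SATB2+"`, `"SATB2-"`), and `stage` (`"prenatal"` /
#' `"postnatal"`). Prenatal ages must be in pcw and within \[4, 40\].
#'
#' @param path TSV path.
#' @param beta Optional beta matrix to cross-check sample identifiers
#'   against.
#' @return A tibble with one row per sample.
#' @export
read_sample_sheet <- function(path, beta = NULL) {
  sheet <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_sample_sheet(sheet, beta)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data frame.
#' @export
validate_sample_sheet <- function(sheet, beta = NULL) {
  sheet <- as_tibble(sheet)
  need <- c("sample_id", "age_value", "age_unit", "sex", "batch")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) mt_abort("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) mt_abort("duplicate sample_id in sheet")
  pre <- if ("stage" %in% names(sheet)) sheet$stage == "prenatal" else sheet$age_unit == "pcw"
  bad <- pre & (sheet$age_unit != "pcw" | sheet$age_value < 4 | sheet$age_value > 40)
  if (any(bad, na.rm = TRUE))
    mt_abort("prenatal sample '%s' must have age in pcw within [4, 40]",
             sheet$sample_id[which(bad)[1]])
  if (!is.null(beta)) {
    absent <- setdiff(sheet$sample_id, colnames(beta))
    if (length(absent))
      mt_abort("sample '%s' absent from the beta matrix", absent[1])
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
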