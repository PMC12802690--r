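#' Read a BED file of open-chromatin peaks
#'
#' Parses a 3+ column BED file (0-based, half-open intervals) into a peak
#' tibble. Intervals are returned sorted by (chromosome, start).
#'
#' @param path BED path.
#' @param cell_type Label attached to every interval (defaults to the file
#'   name without extension).
#' @return A tibble with columns `cell_type`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path, cell_type = NULL) {
  if (is.null(cell_type)) cell_type <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(tibble(cell_type = character(), chrom = character(),
                  start = integer(), end = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) mt_abort("BED line with fewer than 3 fields in '%s'", path)
  chrom <- vapply(parts, `[[`, "", 1)
  start <- as.integer(vapply(parts, `[[`, "", 2))
  end <- as.integer(vapply(parts, `[[`, "", 3))
  if (anyNA(start) || anyNA(end)) mt_abort("non-integer coordinate in '%s'", path)
  bad <- which(start >= end)
  if (length(bad))
    mt_abort("BED interval with start >= end at line %d of '%s'", bad[1], path)
  tibble(cell_type = cell_type, chrom = chrom, start = start, end = end) |>
    arrange(.data$chrom, .data$start)
}

#' @rdname read_bed
#' @param peaks A peak tibble as returned by `read_bed()`.
#' @export
write_bed <- function(peaks, path) {
  write.table(peaks[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Symbols are
#' uppercase-normalised and deduplicated within each set.
#'
#' @param path GMT path.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) mt_abort("GMT line %d has fewer than 3 fields", i)
    sets[[f[1]]] <- unique(toupper(f[-(1:2)]))
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene symbol vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read or write a probe annotation table
#'
#' One row per site: `site_id`, `chrom`, `position` (1-based bp),
#' `gene_symbols` (semicolon-separated, possibly empty), `cgi_class`
#' (island / north_shore / south_shore / north_shelf / south_shelf /
#' open_sea), `genic_class`, `probe_type`.
#'
#' @param path TSV path.
#' @return A tibble, one row per site.
#' @export
read_annotation <- function(path) {
  ann <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param annotation Annotation data frame.
#' @export
validate_annotation <- function(annotation) {
  annotation <- as_tibble(annotation)
  need <- c("site_id", "chrom", "position")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) mt_abort("annotation missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(annotation$site_id)) mt_abort("duplicate site_id in annotation")
  if (any(annotation$position < 1)) mt_abort("annotation positions must be >= 1 (1-based)")
  if (is.na(match("gene_symbols", names(annotation)))) annotation$gene_symbols <- ""
  annotation$gene_symbols[is.na(annotation$gene_symbols)] <- ""
  annotation
}

#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  write.table(as.data.frame(annotation), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Membership of array sites in half-open 0-based intervals: a site at
# 1-based position p overlaps [start, end) iff p - 1 is in [start, end).
sites_in_peaks <- function(annotation, peaks) {
  hit <- rep(FALSE, nrow(annotation))
  p0 <- annotation$position - 1L
  for (ch in unique(peaks$chrom)) {
    idx <- which(annotation$chrom == ch)
    if (!length(idx)) next
    pk <- peaks[peaks$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(pk))) {
      hit[idx] <- hit[idx] | (p0[idx] >= pk$start[k] & p0[idx] < pk$end[k])
    }
  }
  hit
}
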