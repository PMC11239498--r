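# Peak sets, gene annotations and their plain-text formats.
#
# Coordinates are 0-based half-open throughout (BED dialect): a peak
# [start, end) contains base offsets start .. end-1.

#' Construct a peak set
#'
#' A PeakSet is a data.frame of named genomic intervals with optional
#' per-peak scalars (accessibility, GC fraction, motif count, TF binding).
#'
#' @param chrom character chromosome names.
#' @param start,end integer 0-based half-open coordinates, start < end.
#' @param id unique peak identifiers; generated when NULL.
#' @param ... optional per-peak columns (e.g. `gc_fraction`, `accessibility`,
#'   `motif_count`, `tf_bound`), each the same length as `chrom`.
#' @return a data.frame of class `PeakSet`.
#' @export
peak_set <- function(chrom, start, end, id = NULL, ...) {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom names must be non-empty")
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end (0-based half-open)")
  if (is.null(id)) id <- sprintf("peak_%05d", seq_len(n))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("peak ids must be unique")
  extra <- list(...)
  for (nm in names(extra))
    if (length(extra[[nm]]) != n)
      stop(sprintf("column '%s' must have length %d", nm, n))
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = id, stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  if ("gc_fraction" %in% names(df) &&
      any(df$gc_fraction < 0 | df$gc_fraction > 1, na.rm = TRUE))
    stop("gc_fraction must lie in [0, 1]")
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' Construct a gene (TSS) annotation
#'
#' @param gene_id unique gene identifiers.
#' @param chrom chromosome per gene.
#' @param tss transcription start site position (bp).
#' @param strand optional "+"/"-" per gene.
#' @return a data.frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, strand = NULL) {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id, chrom = as.character(chrom),
                   tss = as.numeric(tss),
                   strand = if (is.null(strand)) rep("+", n) else as.character(strand),
                   stringsAsFactors = FALSE)
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

# PeakSet -> GRanges (1-based closed, as GenomicRanges expects).
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    id = peaks$id)
}

intervals_to_granges <- function(chrom, start, end) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start + 1L, end = end))
}

#' Read/write BED files
#'
#' 3-6 column BED plus optional named numeric columns appended after the
#' standard fields. Coordinates stay 0-based half-open.
#'
#' @param file path.
#' @param extra_cols names for numeric columns following the BED6 fields.
#' @return `read_bed`: a `PeakSet`.
#' @export
read_bed <- function(file, extra_cols = character()) {
  df <- utils::read.table(file, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  base_names <- c("chrom", "start", "end", "id", "score", "strand")
  nb <- min(ncol(df) - length(extra_cols), 6L)
  if (nb < 3L) stop("fewer columns than requested extra_cols")
  colnames(df)[seq_len(nb)] <- base_names[seq_len(nb)]
  if (length(extra_cols) > 0L) {
    idx <- nb + seq_along(extra_cols)
    if (max(idx) > ncol(df)) stop("fewer columns than requested extra_cols")
    colnames(df)[idx] <- extra_cols
  }
  args <- list(chrom = df$chrom, start = df$start, end = df$end,
               id = if ("id" %in% colnames(df)) df$id else NULL)
  for (nm in extra_cols) args[[nm]] <- df[[nm]]
  do.call(peak_set, args)
}

#' @rdname read_bed
#' @param peaks a `PeakSet`.
#' @export
write_bed <- function(peaks, file) {
  cols <- c("chrom", "start", "end", "id")
  extra <- setdiff(colnames(peaks), c(cols, "score", "strand"))
  out <- peaks[, c(cols, extra), drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a position weight matrix
#'
#' Whitespace-delimited 4-row matrix (rows A, C, G, T) preceded by a
#' `#ACGT` header line. Values may be counts or frequencies; columns are
#' renormalized downstream.
#'
#' @param file path.
#' @return 4 x W numeric matrix with rownames ACGT.
#' @export
read_pwm <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 4L) stop("PWM file must contain exactly 4 data rows (A, C, G, T)")
  m <- do.call(rbind, lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' @rdname read_pwm
#' @param pwm 4 x W matrix.
#' @export
write_pwm <- function(pwm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#ACGT", con)
  utils::write.table(pwm, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
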