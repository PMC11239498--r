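# The ContactMatrix container and plain-text matrix / pairs I/O.

#' Construct a binned contact matrix
#'
#' Symmetric intra-chromosomal contact counts at a fixed bin size; the
#' substrate of all Hi-C statistics.
#'
#' @param counts square symmetric non-negative matrix.
#' @param bin_size bin width in bp.
#' @param chrom chromosome name.
#' @param weights optional per-bin balancing weights (NA = masked bin).
#' @param balanced logical, whether `counts` is already balanced.
#' @return object of class `ContactMatrix`.
#' @export
contact_matrix <- function(counts, bin_size, chrom = "chr1",
                           weights = NULL, balanced = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (bin_size <= 0) stop("bin_size must be positive")
  if (max(abs(counts - t(counts)), na.rm = TRUE) > 1e-8)
    stop("counts must be symmetric")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  structure(list(chrom = chrom, bin_size = as.numeric(bin_size),
                 counts = counts, weights = weights, balanced = balanced),
            class = "ContactMatrix")
}

#' @export
print.ContactMatrix <- function(x, ...) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %s bp%s, %.3g total contacts\n",
              x$chrom, nrow(x$counts),
              format(x$bin_size, big.mark = ",", scientific = FALSE),
              if (x$balanced) " (balanced)" else "",
              sum(x$counts, na.rm = TRUE)))
  invisible(x)
}

n_bins <- function(cm) nrow(cm$counts)

#' Read/write a contact matrix as COO text
#'
#' Upper-triangle triplets `bin_i bin_j count` (1-based) preceded by a
#' header line `#chrom=<name> #binsize=<int> #nbins=<int>`.
#'
#' @param cm a `ContactMatrix`; `file` a path.
#' @return `read_contact_matrix`: a `ContactMatrix`.
#' @export
write_contact_matrix <- function(cm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#chrom=%s #binsize=%d #nbins=%d", cm$chrom,
                     as.integer(cm$bin_size), n_bins(cm)), con)
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  utils::write.table(data.frame(i = ut[, 1L], j = ut[, 2L],
                                count = cm$counts[ut]),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(file) {
  hdr <- readLines(file, n = 1L)
  get_field <- function(key) {
    m <- regmatches(hdr, regexpr(paste0("#", key, "=[^ ]+"), hdr))
    if (length(m) == 0L) stop("header missing #", key, "=")
    sub(paste0("#", key, "="), "", m)
  }
  chrom <- get_field("chrom")
  bin_size <- as.numeric(get_field("binsize"))
  nb <- as.integer(get_field("nbins"))
  df <- utils::read.table(file, skip = 1L, col.names = c("i", "j", "count"))
  m <- matrix(0, nb, nb)
  m[cbind(df$i, df$j)] <- df$count
  m[cbind(df$j, df$i)] <- df$count
  contact_matrix(m, bin_size = bin_size, chrom = chrom)
}

#' Read/write sparse count matrices as triplets with name sidecars
#'
#' `<prefix>.mtx` holds `row col value` triplets (1-based, with a header
#' line `#nrow= #ncol=`); `<prefix>.rows` and `<prefix>.cols` hold the
#' dimnames, one per line.
#'
#' @param m matrix (dense or Matrix sparse); `prefix` path prefix.
#' @return `read_triplet_matrix`: a sparse `dgCMatrix` with dimnames.
#' @export
write_triplet_matrix <- function(m, prefix) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "TsparseMatrix")
  con <- file(paste0(prefix, ".mtx"), "w")
  writeLines(sprintf("#nrow=%d #ncol=%d", nrow(m), ncol(m)), con)
  utils::write.table(data.frame(i = sm@i + 1L, j = sm@j + 1L, x = sm@x),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  writeLines(rownames(m) %||% as.character(seq_len(nrow(m))),
             paste0(prefix, ".rows"))
  writeLines(colnames(m) %||% as.character(seq_len(ncol(m))),
             paste0(prefix, ".cols"))
  invisible(prefix)
}

#' @rdname write_triplet_matrix
#' @export
read_triplet_matrix <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".mtx"), n = 1L)
  dims <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  df <- utils::read.table(paste0(prefix, ".mtx"), skip = 1L,
                          col.names = c("i", "j", "x"))
  Matrix::sparseMatrix(i = df$i, j = df$j, x = df$x,
                       dims = dims,
                       dimnames = list(readLines(paste0(prefix, ".rows")),
                                       readLines(paste0(prefix, ".cols"))))
}

#' Read Hi-C read-pair records
#'
#' Whitespace-delimited table with columns readID chrA posA fragA chrB
#' posB fragB mapqA mapqB (optional strandA strandB).
#'
#' @param file path.
#' @return data.frame of pair records.
#' @export
read_hic_pairs <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE,
                          comment.char = "#")
  stop_if_missing_cols(df, c("read_id", "chromA", "posA", "fragA",
                             "chromB", "posB", "fragB", "mapqA", "mapqB"),
                       "pairs file")
  df
}

#' Bin filtered read pairs into a contact matrix
#'
#' @param pairs data.frame of (filtered) pair records.
#' @param chrom chromosome to bin (intra-chromosomal pairs only).
#' @param bin_size bin width (bp).
#' @param nbins number of bins; inferred from the data when NULL.
#' @return a `ContactMatrix`.
#' @export
pairs_to_contact_matrix <- function(pairs, chrom, bin_size, nbins = NULL) {
  sel <- pairs$chromA == chrom & pairs$chromB == chrom
  p <- pairs[sel, , drop = FALSE]
  bi <- floor(p$posA / bin_size) + 1L
  bj <- floor(p$posB / bin_size) + 1L
  if (is.null(nbins)) nbins <- max(bi, bj, 1L)
  m <- matrix(0, nbins, nbins)
  for (k in seq_along(bi)) {
    m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1
    if (bi[k] != bj[k]) m[bj[k], bi[k]] <- m[bj[k], bi[k]] + 1
  }
  contact_matrix(m, bin_size = bin_size, chrom = chrom)
}
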