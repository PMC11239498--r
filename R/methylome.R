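# CpG methylation: track container, filtering, aggregation at regions and
# feature-centered average profiles.

#' Construct a methylation track
#'
#' Per-cytosine methylated/total counts with sequence context. Positions
#' must be strictly increasing within each chromosome.
#'
#' @param chrom,pos site coordinates (bp).
#' @param context sequence context, "CpG" or other (e.g. "CHH").
#' @param meth,total methylated and total read counts, 0 <= meth <= total.
#' @return data.frame of class `MethylationTrack` with a `level` column
#'   (meth/total, NA where total is 0).
#' @export
methylation_track <- function(chrom, pos, context, meth, total) {
  if (any(meth > total) || any(meth < 0) || any(total < 0))
    stop("need 0 <= meth <= total")
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   context = as.character(context),
                   meth = as.numeric(meth), total = as.numeric(total),
                   stringsAsFactors = FALSE)
  if (any(unlist(tapply(df$pos, df$chrom, function(p) diff(p) <= 0))))
    stop("positions must be strictly increasing per chromosome")
  df$level <- ifelse(df$total > 0, df$meth / df$total, NA_real_)
  class(df) <- c("MethylationTrack", "data.frame")
  df
}

#' Read/write a methylation track as TSV
#'
#' bedGraph-like columns: chrom, pos, context, meth, total.
#' @param file path; `track` a `MethylationTrack`.
#' @return `read_methylation_track`: a `MethylationTrack`.
#' @export
read_methylation_track <- function(file) {
  df <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("chrom", "pos", "context", "meth", "total"),
                       "methylation file")
  methylation_track(df$chrom, df$pos, df$context, df$meth, df$total)
}

#' @rdname read_methylation_track
#' @export
write_methylation_track <- function(track, file) {
  utils::write.table(track[, c("chrom", "pos", "context", "meth", "total")],
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Filter cytosines to well-covered CpGs
#'
#' Keeps sites in CpG context with total coverage of at least `min_total`
#' (default 10x). Idempotent.
#'
#' @param track a `MethylationTrack`.
#' @param min_total minimum total coverage (inclusive).
#' @return filtered `MethylationTrack`.
#' @export
filter_cpgs <- function(track, min_total = 10L) {
  out <- track[track$context == "CpG" & track$total >= min_total, ,
               drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(track)
  out
}

#' Mean methylation level per region
#'
#' Unweighted mean of per-CpG levels (methylated/total fractions) of the
#' CpGs falling inside each half-open region; with `pooled = TRUE`, pooled
#' counts (sum meth / sum total) instead. Regions without a covered CpG
#' get NA.
#'
#' @param track a filtered `MethylationTrack`.
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @param pooled use pooled counts instead of the mean of fractions.
#' @return numeric vector, one mean level per region.
#' @export
region_methylation <- function(track, regions, pooled = FALSE) {
  vapply(seq_len(nrow(regions)), function(k) {
    sel <- track$chrom == regions$chrom[k] &
      track$pos >= regions$start[k] & track$pos < regions$end[k] &
      track$total > 0
    if (!any(sel)) return(NA_real_)
    if (pooled) sum(track$meth[sel]) / sum(track$total[sel])
    else mean(track$level[sel])
  }, numeric(1L))
}

#' Average methylation profile around feature centers
#'
#' CpGs are assigned to bins by signed distance from the feature midpoint
#' and averaged per bin across all features (strand ignored).
#'
#' @param track a filtered `MethylationTrack`.
#' @param features data.frame with chrom, start, end.
#' @param flank_bp profile half-width around the center (bp).
#' @param n_bins number of profile bins; must be odd so a central bin
#'   exists.
#' @return object of class `MethProfile`: data.frame with `bin_center`
#'   (bp, relative), `mean_level`, `n_cpgs`.
#' @export
meth_profile <- function(track, features, flank_bp = 1000L, n_bins = 21L) {
  if (n_bins %% 2L == 0L) stop("n_bins must be odd so a central bin exists")
  bw <- 2 * flank_bp / n_bins
  centers <- floor((features$start + features$end) / 2)
  lev_acc <- numeric(n_bins); n_acc <- integer(n_bins)
  for (k in seq_len(nrow(features))) {
    sel <- track$chrom == features$chrom[k] & track$total > 0 &
      track$pos >= centers[k] - flank_bp & track$pos < centers[k] + flank_bp
    if (!any(sel)) next
    rel <- track$pos[sel] - centers[k]
    bin <- pmin(pmax(floor((rel + flank_bp) / bw) + 1L, 1L), n_bins)
    lev_acc <- lev_acc + vapply(seq_len(n_bins), function(b)
      sum(track$level[sel][bin == b]), numeric(1L))
    n_acc <- n_acc + tabulate(bin, n_bins)
  }
  out <- data.frame(
    bin_center = (seq_len(n_bins) - (n_bins + 1L) / 2) * bw,
    mean_level = ifelse(n_acc > 0L, lev_acc / n_acc, NA_real_),
    n_cpgs = n_acc)
  class(out) <- c("MethProfile", "data.frame")
  out
}
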