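# Interval analytics on peak sets: overlap classification,
# promoter/distal annotation, covariate-matched background sampling,
# DEG-window overlap fractions.

#' Partition two peak sets by mutual overlap
#'
#' A peak is "shared" iff it overlaps at least `min_overlap_bp` bases with
#' any peak of the other set; otherwise it is condition-specific. This is
#' the peak-universe classification used to compare a TF's binding between
#' two conditions (condition-specific vs shared binding sites).
#'
#' @param a,b `PeakSet`s.
#' @param min_overlap_bp minimum overlap in bp to call two peaks shared
#'   (default 1: any overlap under the half-open convention).
#' @return list with `PeakSet`s `a_specific`, `b_specific`, `shared_a`,
#'   `shared_b` and a `counts` vector.
#' @export
classify_overlap <- function(a, b, min_overlap_bp = 1L) {
  stopifnot(min_overlap_bp >= 1L)
  gra <- peaks_to_granges(a)
  grb <- peaks_to_granges(b)
  only_a <- setdiff(unique(a$chrom), unique(b$chrom))
  if (length(only_a) > 0L)
    log_msg("intervals", "chromosomes only in one set treated as specific: ",
            paste(only_a, collapse = ","))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap_bp))
  sa <- unique(S4Vectors::queryHits(hits))
  sb <- unique(S4Vectors::subjectHits(hits))
  res <- list(
    a_specific = a[setdiff(seq_len(nrow(a)), sa), , drop = FALSE],
    b_specific = b[setdiff(seq_len(nrow(b)), sb), , drop = FALSE],
    shared_a   = a[sort(sa), , drop = FALSE],
    shared_b   = b[sort(sb), , drop = FALSE])
  res$counts <- c(a_specific = nrow(res$a_specific),
                  b_specific = nrow(res$b_specific),
                  shared_a = nrow(res$shared_a),
                  shared_b = nrow(res$shared_b))
  res
}

#' Label peaks as promoter-proximal or promoter-distal
#'
#' A peak is promoter-proximal iff it overlaps the half-open window
#' [tss - w, tss + w) of any gene.
#'
#' @param peaks a `PeakSet`.
#' @param genes a `GeneAnnotation`.
#' @param promoter_halfwidth_bp half-width w of the promoter window (bp).
#' @return character vector, one of "promoter-proximal"/"promoter-distal"
#'   per peak.
#' @export
annotate_promoter_distal <- function(peaks, genes, promoter_halfwidth_bp = 2000L) {
  stopifnot(promoter_halfwidth_bp > 0)
  if (nrow(genes) == 0L) {
    warning("empty gene annotation: all peaks labeled promoter-distal")
    return(rep("promoter-distal", nrow(peaks)))
  }
  w <- promoter_halfwidth_bp
  prom <- intervals_to_granges(genes$chrom,
                               pmax(0, genes$tss - w), genes$tss + w)
  gr <- peaks_to_granges(peaks)
  hit <- suppressWarnings(IRanges::overlapsAny(gr, prom))
  ifelse(hit, "promoter-proximal", "promoter-distal")
}

#' Sample a covariate-matched background peak set
#'
#' For each reference peak, draws `n_per_ref` candidate peaks from the same
#' quantile bin(s) of the matching covariates (e.g. GC fraction and
#' accessibility), never overlapping `exclude`. Bins are defined by
#' candidate-set quantiles; an exhausted bin falls back to the nearest
#' non-empty bin. This emulates the construction of "background accessible
#' regions with similar GC content" used for enrichment nulls.
#'
#' @param candidates `PeakSet` carrying the `match_on` columns.
#' @param reference `PeakSet` to match against.
#' @param match_on character subset of c("gc_fraction", "accessibility").
#' @param n_bins quantile bins per covariate (default 20).
#' @param n_per_ref candidates drawn per reference peak.
#' @param exclude optional `PeakSet`; sampled peaks never overlap it.
#' @param seed integer RNG seed.
#' @return `PeakSet` of sampled candidates with a `matched_to` column.
#' @export
sample_matched_background <- function(candidates, reference,
                                      match_on = "gc_fraction",
                                      n_bins = 20L, n_per_ref = 1L,
                                      exclude = NULL, seed = 1L) {
  stopifnot(n_bins >= 2L, n_per_ref >= 1L, length(match_on) >= 1L)
  stop_if_missing_cols(candidates, match_on, "candidates")
  stop_if_missing_cols(reference, match_on, "reference")
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ov <- suppressWarnings(IRanges::overlapsAny(
      peaks_to_granges(candidates), peaks_to_granges(exclude)))
    keep <- !ov
  }
  pool <- candidates[keep, , drop = FALSE]
  if (nrow(pool) == 0L) stop("no candidates remain after applying exclude")

  # quantile bins defined on the candidate pool, shared with the reference
  bin_of <- function(x, edges) {
    b <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), length(edges) - 1L)
  }
  edges <- lapply(match_on, function(cv)
    unique(stats::quantile(pool[[cv]], probs = seq(0, 1, length.out = n_bins + 1L),
                           na.rm = TRUE, names = FALSE)))
  names(edges) <- match_on
  pool_bins <- sapply(match_on, function(cv) bin_of(pool[[cv]], edges[[cv]]))
  ref_bins <- sapply(match_on, function(cv) bin_of(reference[[cv]], edges[[cv]]))
  pool_bins <- matrix(pool_bins, nrow = nrow(pool))
  ref_bins <- matrix(ref_bins, nrow = nrow(reference))

  picks <- with_seed(seed, {
    fell_back <- 0L
    out <- vector("list", nrow(reference))
    for (i in seq_len(nrow(reference))) {
      # expand search radius in max-metric over bin indices until filled
      dmax <- apply(abs(sweep(pool_bins, 2L, ref_bins[i, ])), 1L, max)
      for (rad in 0:(n_bins - 1L)) {
        inbin <- which(dmax <= rad)
        if (length(inbin) >= n_per_ref) {
          if (rad > 0L) fell_back <- fell_back + 1L
          out[[i]] <- if (length(inbin) == n_per_ref) inbin else
            sample(inbin, n_per_ref, replace = FALSE)
          break
        }
      }
      if (is.null(out[[i]]))
        stop("candidate pool exhausted: cannot draw ", n_per_ref,
             " matched peaks for reference peak ", reference$id[i])
    }
    if (fell_back > 0L)
      log_msg("intervals", fell_back, " reference peak(s) used nearest-bin fallback")
    out
  })
  idx <- unlist(picks)
  res <- pool[idx, , drop = FALSE]
  res$matched_to <- rep(reference$id, each = n_per_ref)
  rownames(res) <- NULL
  class(res) <- c("PeakSet", "data.frame")
  res
}

#' Fraction of differential genes with a peak near the TSS
#'
#' For each peak category and each direction of regulation, the percentage
#' of genes whose half-open window [tss - window, tss + window) intersects
#' at least one category peak.
#'
#' @param degs data.frame with columns `gene_id` and `direction`
#'   (levels "up", "down", "ns").
#' @param peaks_by_category named list of `PeakSet`s.
#' @param genes a `GeneAnnotation`.
#' @param window_bp window half-width around the TSS (bp).
#' @return data.frame category x direction with percentages (NA for empty
#'   strata, with a warning).
#' @export
deg_peak_overlap_fraction <- function(degs, peaks_by_category, genes,
                                      window_bp = 100000L) {
  stopifnot(window_bp > 0)
  stop_if_missing_cols(degs, c("gene_id", "direction"), "degs")
  bad <- setdiff(unique(degs$direction), c("up", "down", "ns"))
  if (length(bad) > 0L)
    stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  gi <- match(degs$gene_id, genes$gene_id)
  if (anyNA(gi)) stop("degs reference genes absent from the annotation")
  win <- intervals_to_granges(genes$chrom[gi],
                              pmax(0, genes$tss[gi] - window_bp),
                              genes$tss[gi] + window_bp)
  dirs <- c("up", "down", "ns")
  out <- expand.grid(category = names(peaks_by_category), direction = dirs,
                     stringsAsFactors = FALSE)
  out$percent <- NA_real_
  empty <- dirs[!dirs %in% degs$direction]
  if (length(empty) > 0L)
    warning("no genes with direction ", paste(empty, collapse = "/"),
            "; percentage undefined")
  for (cat in names(peaks_by_category)) {
    hit <- suppressWarnings(IRanges::overlapsAny(
      win, peaks_to_granges(peaks_by_category[[cat]])))
    for (d in setdiff(dirs, empty)) {
      sel <- degs$direction == d
      row <- out$category == cat & out$direction == d
      out$percent[row] <- 100 * sum(hit[sel]) / sum(sel)
    }
  }
  out
}
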