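# Motif scanning and enrichment.
#
# Scoring is log-odds against a uniform background. Column frequencies are
# smoothed with a uniform 0.25 pseudo-frequency, f' = (f + 0.25) / 2, so no
# base has zero probability; threshold is a fraction of the maximum
# attainable score. 'N' contributes its background expectation
# (sum_b 0.25 * S[b, j]).

DNA_BASES <- c("A", "C", "G", "T")

# motif -> 5 x W log2-odds score matrix (rows A,C,G,T,N).
motif_score_matrix <- function(motif) {
  if (is.character(motif)) {
    stopifnot(length(motif) == 1L, nchar(motif) >= 2L)
    ch <- strsplit(toupper(motif), "")[[1]]
    if (!all(ch %in% DNA_BASES)) stop("consensus must contain only ACGT")
    pfm <- sapply(ch, function(b) as.numeric(DNA_BASES == b))
    rownames(pfm) <- DNA_BASES
  } else {
    pfm <- as.matrix(motif)
    if (nrow(pfm) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
    rownames(pfm) <- DNA_BASES
    pfm <- sweep(pfm, 2L, colSums(pfm), "/")  # counts -> frequencies
  }
  fr <- (pfm + 0.25) / 2
  s <- log2(fr / 0.25)
  rbind(s, N = colSums(0.25 * s))
}

reverse_complement <- function(seqs) {
  vapply(seqs, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# All (start, strand, score) hits with score >= thr, one row per position.
scan_hits <- function(seq, smat, thr) {
  w <- ncol(smat)
  ch <- strsplit(toupper(seq), "")[[1]]
  idx <- match(ch, c(DNA_BASES, "N"))
  if (anyNA(idx)) stop("sequence contains characters outside ACGTN")
  n <- length(idx)
  if (n < w) return(data.frame(start = integer(), strand = character(),
                               score = numeric()))
  ns <- n - w + 1L
  fwd <- numeric(ns); rev_ <- numeric(ns)
  # reverse-complement scan == scanning the reverse-complemented matrix
  rc <- smat[c(4:1, 5L), w:1, drop = FALSE]
  for (j in seq_len(w)) {
    col <- idx[j:(j + ns - 1L)]
    fwd <- fwd + smat[col + (j - 1L) * 5L]
    rev_ <- rev_ + rc[col + (j - 1L) * 5L]
  }
  fi <- which(fwd >= thr); ri <- which(rev_ >= thr)
  hits <- rbind(
    data.frame(start = fi, strand = rep("+", length(fi)), score = fwd[fi]),
    data.frame(start = ri, strand = rep("-", length(ri)), score = rev_[ri]))
  # greedy left-to-right, "+" before "-" at equal starts
  hits[order(hits$start, hits$strand), , drop = FALSE]
}

#' Count motif matches per sequence
#'
#' Counts non-overlapping matches on both strands whose log-odds score
#' reaches `score_fraction` times the maximum attainable score; matches are
#' selected greedily left to right (ties: leftmost start, then + strand).
#'
#' @param sequences named character vector of ACGTN sequences (typically
#'   per-peak).
#' @param motif consensus string or 4 x W position frequency/count matrix.
#' @param score_fraction fraction of the maximal score required (default 0.8).
#' @return integer vector of counts, named like `sequences`.
#' @export
count_motif_hits <- function(sequences, motif, score_fraction = 0.8) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  smat <- motif_score_matrix(motif)
  w <- ncol(smat)
  if (any(nchar(sequences) < w))
    stop("motif width exceeds the shortest sequence")
  thr <- score_fraction * sum(apply(smat[1:4, , drop = FALSE], 2L, max))
  vapply(sequences, function(s) {
    h <- scan_hits(s, smat, thr)
    cnt <- 0L; nextfree <- 1L
    for (r in seq_len(nrow(h))) {
      if (h$start[r] >= nextfree) {
        cnt <- cnt + 1L
        nextfree <- h$start[r] + w
      }
    }
    cnt
  }, integer(1L))
}

#' Motif enrichment of a foreground peak set over a background
#'
#' Fold = (fraction of foreground peaks with >= 1 hit) / (fraction of
#' background peaks with >= 1 hit), reported as log2. The p-value is the
#' one-sided hypergeometric upper tail, treating the foreground as a draw
#' from the pooled foreground+background universe of peaks, with peaks
#' carrying a hit as successes.
#'
#' @param fg_sequences,bg_sequences character vectors of peak sequences.
#' @param motif consensus string or 4 x W matrix.
#' @param score_fraction see [count_motif_hits()].
#' @return list(log2_fold, p, fg_hits, bg_hits, fg_n, bg_n). A zero
#'   background hit rate yields log2_fold = Inf with the exact tail p.
#' @export
motif_enrichment <- function(fg_sequences, bg_sequences, motif,
                             score_fraction = 0.8) {
  if (length(fg_sequences) == 0L || length(bg_sequences) == 0L)
    stop("foreground and background must be non-empty")
  kf <- sum(count_motif_hits(fg_sequences, motif, score_fraction) > 0L)
  kb <- sum(count_motif_hits(bg_sequences, motif, score_fraction) > 0L)
  nf <- length(fg_sequences); nb <- length(bg_sequences)
  fold <- (kf / nf) / (kb / nb)
  p <- stats::phyper(kf - 1L, kf + kb, nf + nb - kf - kb, nf,
                     lower.tail = FALSE)
  list(log2_fold = log2(fold), p = p,
       fg_hits = kf, bg_hits = kb, fg_n = nf, bg_n = nb)
}
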