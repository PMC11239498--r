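# Hi-C feature statistics: pair filtering, balancing, distance decay,
# A/B compartments and strength, insulation/TAD boundaries, rescaled TAD
# aggregation, aggregate contact analysis at anchor pairs, per-pair scores.

#' Filter Hi-C read pairs
#'
#' Keeps uniquely mapping pairs (both sides mapq > 30), drops
#' intra-chromosomal pairs mapped to the same restriction fragment or
#' separated by less than 1 kb, and removes exact PCR duplicates (same
#' chromosomes, positions and, when present, strands), keeping the first.
#'
#' @param records data.frame with columns read_id, chromA, posA, fragA,
#'   chromB, posB, fragB, mapqA, mapqB (optional strandA/strandB).
#' @param min_mapq keep only pairs with both mapq strictly greater.
#' @param min_separation_bp minimum intra-chromosomal separation (bp).
#' @return the kept records, with a `filter_stats` attribute.
#' @export
filter_hic_pairs <- function(records, min_mapq = 30L,
                             min_separation_bp = 1000L) {
  stop_if_missing_cols(records, c("read_id", "chromA", "posA", "fragA",
                                  "chromB", "posB", "fragB",
                                  "mapqA", "mapqB"), "pair records")
  bad <- which(is.na(records$posA) | is.na(records$posB) |
                 records$posA < 0 | records$posB < 0 |
                 is.na(records$mapqA) | is.na(records$mapqB))
  if (length(bad) > 0L)
    stop("malformed pair record at line ", bad[1L])
  n0 <- nrow(records)
  keep_mapq <- records$mapqA > min_mapq & records$mapqB > min_mapq
  intra <- records$chromA == records$chromB
  same_frag <- intra & records$fragA == records$fragB
  close_cis <- intra & abs(records$posA - records$posB) < min_separation_bp
  kept <- records[keep_mapq & !same_frag & !close_cis, , drop = FALSE]
  key <- paste(kept$chromA, kept$posA, kept$chromB, kept$posB,
               if ("strandA" %in% colnames(kept)) kept$strandA else "",
               if ("strandB" %in% colnames(kept)) kept$strandB else "")
  dup <- duplicated(key)
  kept <- kept[!dup, , drop = FALSE]
  attr(kept, "filter_stats") <- c(
    input = n0, low_mapq = sum(!keep_mapq), same_fragment = sum(same_frag),
    close_cis = sum(close_cis & !same_frag), duplicates = sum(dup),
    kept = nrow(kept))
  kept
}

#' Balance a contact matrix to uniform coverage
#'
#' Iterative proportional correction: finds per-bin weights w such that
#' diag(w) M diag(w) has (near-)equal row sums over unmasked bins. This is
#' the same doubly-stochastic scaling that Knight-Ruiz balancing reaches
#' for symmetric non-negative matrices. Sparse bins (coverage below
#' `mask_frac` of the median) are masked first and carry NA weights.
#'
#' @param cm a `ContactMatrix`.
#' @param tol convergence tolerance on the coefficient of variation of
#'   unmasked row sums.
#' @param max_iter iteration cap.
#' @param mask_frac sparse-bin mask threshold as a fraction of median
#'   coverage.
#' @return a balanced `ContactMatrix` (counts rescaled so the total sum is
#'   preserved; masked rows/columns NA) with `weights` filled.
#' @export
balance_matrix <- function(cm, tol = 1e-6, max_iter = 500L,
                           mask_frac = 0.02) {
  m <- cm$counts
  cov <- rowSums(m, na.rm = TRUE)
  med <- stats::median(cov[cov > 0])
  masked <- cov < mask_frac * med | cov == 0
  if (all(masked)) stop("all bins masked; nothing to balance")
  sub <- m[!masked, !masked, drop = FALSE]
  w <- rep(1, nrow(sub))
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    s <- as.vector(sub %*% w) * w
    cv <- stats::sd(s) / mean(s)
    if (is.finite(cv) && cv < tol) { ok <- TRUE; break }
    w <- w / sqrt(s / mean(s))
  }
  if (!ok)
    stop("balancing did not converge in ", max_iter,
         " iterations; increase mask_frac to mask more sparse bins")
  bal_sub <- sub * outer(w, w)
  bal_sub <- bal_sub * sum(sub) / sum(bal_sub)  # preserve total mass
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[!masked, !masked] <- bal_sub
  weights <- rep(NA_real_, nrow(m))
  weights[!masked] <- w
  contact_matrix(out, bin_size = cm$bin_size, chrom = cm$chrom,
                 weights = weights, balanced = TRUE)
}

# Mean contact per integer bin distance d = 0 .. n-1 (index d+1).
mean_by_distance <- function(counts) {
  n <- nrow(counts)
  vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    mean(counts[cbind(i, i + d)], na.rm = TRUE)
  }, numeric(1L))
}

#' Contact probability as a function of genomic distance
#'
#' Mean contact per log-spaced distance bin, plus the normalized
#' contact-probability curve P(s) ("obs/sum": per-bin contact mass divided
#' by the total, summing to 1). The per-bin-distance mean profile is also
#' returned and serves as the expected model E(s) for all obs/exp
#' statistics.
#'
#' @param cm a `ContactMatrix`.
#' @param n_log_bins number of log-spaced distance bins.
#' @return object of class `DistanceDecay`: list with `bin_lo`, `bin_hi`,
#'   `bin_mid` (bp, geometric mid), `mean_count`, `p_s` (sums to 1),
#'   `expected_by_dist` (length n_bins, index d+1 for bin distance d).
#' @export
distance_decay <- function(cm, n_log_bins = 30L) {
  m <- cm$counts
  n <- nrow(m)
  if (sum(m, na.rm = TRUE) == 0) stop("empty contact matrix")
  ebd <- mean_by_distance(m)
  d_bp <- (1:(n - 1L)) * cm$bin_size
  npairs <- (n - 1L):1L
  tot_d <- ebd[-1L] * npairs  # total contacts at each distance (na-mean * n)
  edges <- exp(seq(log(cm$bin_size * 0.999), log(max(d_bp) * 1.001),
                   length.out = n_log_bins + 1L))
  bin <- findInterval(d_bp, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tot <- tapply(tot_d, bin, sum)
  npb <- tapply(npairs, bin, sum)
  used <- as.integer(names(tot))
  if (length(used) < 2L) stop("need at least 2 populated distance bins")
  mean_count <- as.numeric(tot / npb)
  p_s <- as.numeric(tot / sum(tot))
  structure(list(bin_lo = edges[used], bin_hi = edges[used + 1L],
                 bin_mid = sqrt(edges[used] * edges[used + 1L]),
                 mean_count = mean_count, p_s = p_s,
                 expected_by_dist = ebd, bin_size = cm$bin_size,
                 chrom = cm$chrom), class = "DistanceDecay")
}

#' Fitted power-law slope of a distance-decay curve
#'
#' Ordinary least squares of log(mean count) on log(distance) over
#' populated bins, optionally restricted to a bp range.
#'
#' @param dd a `DistanceDecay`.
#' @param min_bp,max_bp optional distance range.
#' @return slope (alpha of s^-alpha is -slope).
#' @export
power_law_slope <- function(dd, min_bp = NULL, max_bp = NULL) {
  sel <- dd$mean_count > 0
  if (!is.null(min_bp)) sel <- sel & dd$bin_mid >= min_bp
  if (!is.null(max_bp)) sel <- sel & dd$bin_mid <= max_bp
  stats::coef(stats::lm(log(dd$mean_count[sel]) ~ log(dd$bin_mid[sel])))[[2L]]
}

# Expected matrix from the per-distance mean profile.
expected_matrix <- function(cm, expected = NULL) {
  ebd <- if (is.null(expected)) mean_by_distance(cm$counts)
         else if (inherits(expected, "DistanceDecay")) expected$expected_by_dist
         else expected
  n <- n_bins(cm)
  matrix(ebd[abs(outer(seq_len(n), seq_len(n), "-")) + 1L], n, n)
}

#' A/B compartments and compartment strength
#'
#' The compartment eigenvector is the dominant eigenvector of the Pearson
#' correlation matrix of obs/exp contacts; bins are labeled A/B by its
#' sign, oriented (when an orientation track is given) so that A bins have
#' the higher track mean. Compartment strength is the ratio of the mean
#' obs/exp contact within compartments (A-A plus B-B) to the mean between
#' compartments (A-B), over intra-chromosomal pairs separated by at least
#' `min_dist_bp`; the raw observed-count sum ratio is also reported. A
#' Q x Q saddle (mean obs/exp over eigenvector quantile pairs) is emitted
#' for inspection.
#'
#' @param cm a `ContactMatrix` (balanced recommended).
#' @param orientation_track optional per-bin scalar (e.g. gene density or
#'   accessibility) used to orient the sign of the eigenvector.
#' @param min_dist_bp minimum pair separation entering the strength ratio
#'   (default 10 Mb).
#' @param n_quantiles saddle quantiles Q.
#' @return object of class `CompartmentResult`: list(e1, labels, strength,
#'   strength_raw, saddle, oriented, used_bins).
#' @export
compartments <- function(cm, orientation_track = NULL, min_dist_bp = 1e7,
                         n_quantiles = 5L) {
  m <- cm$counts
  n <- nrow(m)
  e <- expected_matrix(cm)
  oe <- m / e
  oe[!is.finite(oe)] <- NA
  usable <- which(apply(oe, 1L, function(r) {
    v <- r[is.finite(r)]
    length(v) > 1L && stats::sd(v) > 0 && any(v > 0)
  }))
  if (length(usable) < 10L) stop("fewer than 10 usable bins")
  cc <- suppressWarnings(stats::cor(oe[usable, usable],
                                    use = "pairwise.complete.obs"))
  cc[!is.finite(cc)] <- 0
  eig <- eigen(cc, symmetric = TRUE)
  e1_sub <- eig$vectors[, 1L]
  oriented <- FALSE
  if (!is.null(orientation_track)) {
    tr <- orientation_track[usable]
    hi <- mean(tr[e1_sub > 0], na.rm = TRUE)
    lo <- mean(tr[e1_sub <= 0], na.rm = TRUE)
    if (is.finite(hi) && is.finite(lo) && hi < lo) e1_sub <- -e1_sub
    oriented <- TRUE
  }
  e1 <- rep(NA_real_, n); e1[usable] <- e1_sub
  labels <- rep(NA_character_, n)
  labels[usable] <- ifelse(e1_sub > 0, "A", "B")

  idx <- which(abs(outer(seq_len(n), seq_len(n), "-")) * cm$bin_size >=
                 min_dist_bp & upper.tri(m), arr.ind = TRUE)
  ok <- !is.na(labels[idx[, 1L]]) & !is.na(labels[idx[, 2L]])
  idx <- idx[ok, , drop = FALSE]
  same <- labels[idx[, 1L]] == labels[idx[, 2L]]
  oe_p <- oe[idx]; obs_p <- m[idx]
  strength <- mean(oe_p[same], na.rm = TRUE) / mean(oe_p[!same], na.rm = TRUE)
  strength_raw <- sum(obs_p[same], na.rm = TRUE) /
    sum(obs_p[!same], na.rm = TRUE)

  q <- cut(rank(e1_sub, ties.method = "first"), n_quantiles, labels = FALSE)
  saddle <- matrix(NA_real_, n_quantiles, n_quantiles)
  oe_sub <- oe[usable, usable]
  dist_sub <- abs(outer(seq_along(usable), seq_along(usable), "-"))
  for (a in seq_len(n_quantiles)) for (b in seq_len(n_quantiles)) {
    cells <- oe_sub[q == a, q == b, drop = FALSE]
    dd <- dist_sub[q == a, q == b, drop = FALSE]
    saddle[a, b] <- mean(cells[dd >= 2L], na.rm = TRUE)
  }
  structure(list(e1 = e1, labels = labels, strength = strength,
                 strength_raw = strength_raw, saddle = saddle,
                 oriented = oriented, used_bins = usable),
            class = "CompartmentResult")
}

# Local minima of a score vector with topographic prominence and a
# minimum separation (keep the deeper of two close minima; tie: leftmost).
find_score_minima <- function(score, min_prominence, min_sep) {
  n <- length(score)
  cand <- integer(0)
  for (b in 2:(n - 1L)) {
    s <- score[b]
    if (is.na(s) || is.na(score[b - 1L]) || is.na(score[b + 1L])) next
    if (s < score[b - 1L] && s <= score[b + 1L]) cand <- c(cand, b)
  }
  prom <- vapply(cand, function(b) {
    s <- score[b]
    side_high <- function(dir) {
      hi <- -Inf
      i <- b + dir
      while (i >= 1L && i <= n && !is.na(score[i]) && score[i] >= s) {
        hi <- max(hi, score[i]); i <- i + dir
      }
      if (i >= 1L && i <= n && !is.na(score[i])) hi else
        max(hi, score[i - dir])  # ran off the profile: use max seen
    }
    min(side_high(-1L), side_high(1L)) - s
  }, numeric(1L))
  keep <- cand[prom >= min_prominence]
  # enforce minimum separation
  if (length(keep) > 1L) {
    repeat {
      gaps <- diff(keep)
      close_i <- which(gaps < min_sep)
      if (length(close_i) == 0L) break
      i <- close_i[1L]
      drop <- if (score[keep[i + 1L]] < score[keep[i]]) i else i + 1L
      keep <- keep[-drop]
    }
  }
  keep
}

#' Insulation score and TAD boundary calling
#'
#' The insulation score at bin b is the log2 ratio of the mean observed
#' contacts in the w x w square spanning [b-w, b) x [b, b+w) (pairs
#' crossing the prospective boundary) to the chromosome-wide mean of that
#' statistic. TAD boundaries are local minima of the score with
#' topographic prominence of at least `min_prominence` log2 units; of two
#' minima closer than w bins the deeper is kept (ties: leftmost). Bins
#' within w of the chromosome ends carry missing scores.
#'
#' @param cm a `ContactMatrix`.
#' @param w window size in bins (default 10).
#' @param min_prominence boundary prominence threshold (log2 units).
#' @return object of class `InsulationProfile`: list(score, w, boundaries,
#'   bin_size, chrom).
#' @export
insulation <- function(cm, w = 10L, min_prominence = 0.2) {
  m <- cm$counts
  n <- nrow(m)
  if (w < 2L) stop("w must be >= 2")
  if (n < 4L * w) stop("chromosome too short for window w = ", w)
  stat <- rep(NA_real_, n)
  for (b in (w + 1L):(n - w + 1L))
    stat[b] <- mean(m[(b - w):(b - 1L), b:(b + w - 1L)], na.rm = TRUE)
  score <- log2(stat / mean(stat, na.rm = TRUE))
  boundaries <- find_score_minima(score, min_prominence, min_sep = w)
  structure(list(score = score, w = w, boundaries = boundaries,
                 bin_size = cm$bin_size, chrom = cm$chrom),
            class = "InsulationProfile")
}

# NA-aware bilinear rescaling of a square matrix to g x g.
bilinear_rescale <- function(m, g) {
  p <- nrow(m)
  s <- (seq_len(g) - 0.5) * p / g + 0.5
  i0 <- pmin(pmax(floor(s), 1L), p)
  i1 <- pmin(i0 + 1L, p)
  fr <- pmin(pmax(s - i0, 0), 1)
  out <- matrix(NA_real_, g, g)
  for (a in seq_len(g)) for (b in seq_len(g)) {
    v <- c(m[i0[a], i0[b]], m[i1[a], i0[b]], m[i0[a], i1[b]], m[i1[a], i1[b]])
    wt <- c((1 - fr[a]) * (1 - fr[b]), fr[a] * (1 - fr[b]),
            (1 - fr[a]) * fr[b], fr[a] * fr[b])
    ok <- !is.na(v)
    if (any(ok) && sum(wt[ok]) > 0)
      out[a, b] <- sum(v[ok] * wt[ok]) / sum(wt[ok])
  }
  out
}

#' Average rescaled contact enrichment across TADs
#'
#' Each TAD's log2 obs/exp submatrix, extended by one TAD length on each
#' side, is rescaled to a fixed grid by bilinear interpolation and
#' averaged across TADs. TADs shorter than 3 bins are skipped.
#'
#' @param cm a `ContactMatrix`.
#' @param tads data.frame with `start`, `end` in bp (0-based half-open).
#' @param n_rescaled_bins grid cells per TAD length (the output grid is
#'   3x this, covering flank + TAD + flank).
#' @param expected optional `DistanceDecay` or per-distance vector.
#' @return list(map = averaged log2 obs/exp grid, n_used, n_skipped).
#' @export
aggregate_tads <- function(cm, tads, n_rescaled_bins = 30L, expected = NULL) {
  m <- cm$counts
  n <- nrow(m)
  e <- expected_matrix(cm, expected)
  l2 <- log2((m + 1) / (e + 1))
  g <- 3L * n_rescaled_bins
  acc <- matrix(0, g, g); cnt <- matrix(0, g, g)
  used <- 0L; skipped <- 0L
  for (k in seq_len(nrow(tads))) {
    b0 <- floor(tads$start[k] / cm$bin_size) + 1L
    b1 <- ceiling(tads$end[k] / cm$bin_size)
    len <- b1 - b0 + 1L
    if (len < 3L) { skipped <- skipped + 1L; next }
    lo <- b0 - len; hi <- b1 + len
    sub <- matrix(NA_real_, hi - lo + 1L, hi - lo + 1L)
    rin <- max(lo, 1L):min(hi, n)
    sub[rin - lo + 1L, rin - lo + 1L] <- l2[rin, rin]
    rs <- bilinear_rescale(sub, g)
    ok <- !is.na(rs)
    acc[ok] <- acc[ok] + rs[ok]
    cnt[ok] <- cnt[ok] + 1L
    used <- used + 1L
  }
  if (used == 0L) stop("no usable TADs (all shorter than 3 bins?)")
  if (skipped > 0L) log_msg("hic", skipped, " TAD(s) shorter than 3 bins skipped")
  map <- acc / cnt
  map[cnt == 0L] <- NA
  list(map = map, n_used = used, n_skipped = skipped)
}

#' Aggregate contact enrichment at anchor pairs (APA)
#'
#' Averages log2((obs + 1) / (E(s) + 1)) over (2W+1)^2 windows centered on
#' each anchor pair. The center enrichment is the mean of the central 3x3
#' block minus the mean of the four 3x3 corner blocks (averaged over
#' corners), in log2 units. Pairs separated by no more than 2W+1 bins, or
#' with an anchor within W bins of a chromosome end, are excluded.
#'
#' @param cm a `ContactMatrix`.
#' @param anchor_pairs 2-column matrix/data.frame of 1-based bin indices.
#' @param W flank in bins (window is (2W+1) x (2W+1)).
#' @param expected optional `DistanceDecay` or per-distance vector.
#' @return object of class `APAResult`: list(map, center_enrichment,
#'   n_pairs, n_excluded).
#' @export
apa <- function(cm, anchor_pairs, W = 10L, expected = NULL) {
  m <- cm$counts
  n <- nrow(m)
  ap <- as.matrix(anchor_pairs)[, 1:2, drop = FALSE]
  i <- pmin(ap[, 1L], ap[, 2L]); j <- pmax(ap[, 1L], ap[, 2L])
  ok <- (j - i) > (2L * W + 1L) & i > W & j > W & i <= n - W & j <= n - W
  if (sum(!ok) > 0L)
    log_msg("hic", sum(!ok), " anchor pair(s) excluded (too close or near edge)")
  if (!any(ok)) stop("zero usable anchor pairs")
  i <- i[ok]; j <- j[ok]
  e <- expected_matrix(cm, expected)
  win <- 2L * W + 1L
  acc <- matrix(0, win, win); cnt <- matrix(0, win, win)
  for (k in seq_along(i)) {
    rows <- (i[k] - W):(i[k] + W)
    cols <- (j[k] - W):(j[k] + W)
    v <- log2((m[rows, cols] + 1) / (e[rows, cols] + 1))
    okc <- is.finite(v)
    acc[okc] <- acc[okc] + v[okc]
    cnt[okc] <- cnt[okc] + 1L
  }
  map <- acc / cnt
  map[cnt == 0L] <- NA
  ctr <- W + 1L
  center <- mean(map[(ctr - 1L):(ctr + 1L), (ctr - 1L):(ctr + 1L)],
                 na.rm = TRUE)
  corner_blocks <- list(c(1L, 3L), c(win - 2L, win))
  corners <- vapply(corner_blocks, function(r)
    vapply(corner_blocks, function(c2)
      mean(map[r[1L]:r[2L], c2[1L]:c2[2L]], na.rm = TRUE), numeric(1L)),
    numeric(2L))
  structure(list(map = map, center_enrichment = center - mean(corners),
                 n_pairs = length(i), n_excluded = sum(!ok)),
            class = "APAResult")
}

#' Per-pair contact score in a fixed window
#'
#' For each feature pair, the log2 ratio of observed to expected contacts
#' summed over the bins covered by a `window_bp` window centered on the
#' pair, with a pseudocount of 1 on both sides.
#'
#' @param cm a `ContactMatrix`.
#' @param pairs data.frame/matrix with two bp-coordinate columns (x, y).
#' @param window_bp window size centered on the pair (default 10 kb).
#' @param expected optional `DistanceDecay` or per-distance vector.
#' @return numeric score per pair.
#' @export
pair_contact_scores <- function(cm, pairs, window_bp = 10000, expected = NULL) {
  m <- cm$counts
  n <- nrow(m)
  e <- expected_matrix(cm, expected)
  p <- as.matrix(pairs)[, 1:2, drop = FALSE]
  half <- window_bp / 2
  vapply(seq_len(nrow(p)), function(k) {
    rb <- (floor((p[k, 1L] - half) / cm$bin_size) + 1L):
          (ceiling((p[k, 1L] + half) / cm$bin_size))
    cb <- (floor((p[k, 2L] - half) / cm$bin_size) + 1L):
          (ceiling((p[k, 2L] + half) / cm$bin_size))
    if (min(rb, cb) < 1L || max(rb, cb) > n)
      stop("pair ", k, " falls outside the contact matrix")
    log2((sum(m[rb, cb, drop = FALSE], na.rm = TRUE) + 1) /
           (sum(e[rb, cb, drop = FALSE], na.rm = TRUE) + 1))
  }, numeric(1L))
}
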