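# Independent brute-force oracles used to check the package's
# implementations on small inputs, plus tiny fixture builders.

options(epiremod.quiet = TRUE)

# all-pairs interval overlap oracle (0-based half-open), >= min_bp overlap
oracle_overlap_any <- function(peaks_a, peaks_b, min_bp = 1L) {
  vapply(seq_len(nrow(peaks_a)), function(i) {
    any(vapply(seq_len(nrow(peaks_b)), function(j) {
      if (peaks_a$chrom[i] != peaks_b$chrom[j]) return(FALSE)
      ov <- min(peaks_a$end[i], peaks_b$end[j]) -
        max(peaks_a$start[i], peaks_b$start[j])
      ov >= min_bp
    }, logical(1L)))
  }, logical(1L))
}

# exact hypergeometric upper tail P(X >= x): population N with K successes,
# m draws, by direct combinatorial summation
oracle_hyper_tail <- function(x, K, N, m) {
  i <- max(x, max(0L, m - (N - K))):min(K, m)
  if (x > min(K, m)) return(0)
  sum(choose(K, i) * choose(N - K, m - i)) / choose(N, m)
}

# brute-force APA: explicit loops over pairs and window cells
oracle_apa <- function(counts, expected_by_dist, pairs, W) {
  win <- 2L * W + 1L
  acc <- matrix(0, win, win); nacc <- matrix(0, win, win)
  for (k in seq_len(nrow(pairs))) {
    i <- min(pairs[k, 1L], pairs[k, 2L]); j <- max(pairs[k, 1L], pairs[k, 2L])
    for (a in -W:W) for (b in -W:W) {
      o <- counts[i + a, j + b]
      e <- expected_by_dist[abs((i + a) - (j + b)) + 1L]
      v <- log2((o + 1) / (e + 1))
      acc[a + W + 1L, b + W + 1L] <- acc[a + W + 1L, b + W + 1L] + v
      nacc[a + W + 1L, b + W + 1L] <- nacc[a + W + 1L, b + W + 1L] + 1L
    }
  }
  map <- acc / nacc
  ctr <- W + 1L
  center <- mean(map[(ctr - 1L):(ctr + 1L), (ctr - 1L):(ctr + 1L)])
  corners <- c(mean(map[1:3, 1:3]), mean(map[1:3, (win - 2L):win]),
               mean(map[(win - 2L):win, 1:3]),
               mean(map[(win - 2L):win, (win - 2L):win]))
  list(map = map, center_enrichment = center - mean(corners))
}

# brute-force compartment strength: loop over all qualifying cells
oracle_compartment_strength <- function(counts, expected_by_dist, labels,
                                        bin_size, min_dist_bp = 1e7) {
  n <- nrow(counts)
  oe_w <- oe_b <- c()
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    if ((j - i) * bin_size < min_dist_bp) next
    if (is.na(labels[i]) || is.na(labels[j])) next
    oe <- counts[i, j] / expected_by_dist[j - i + 1L]
    if (labels[i] == labels[j]) oe_w <- c(oe_w, oe) else oe_b <- c(oe_b, oe)
  }
  mean(oe_w) / mean(oe_b)
}

# expected counts of the contact-map generator, structure-free
analytic_decay <- function(config) {
  config$contact_depth *
    pmax(0:(config$n_bins - 1L), 1L)^(-config$decay_exponent)
}

# minimal MetacellMatrix with constant per-row library size, so CP10K+log1p
# is the same monotone map on every row
make_toy_metacells <- function(n_meta = 12L, n_noise = 60L, seed = 42L) {
  set.seed(seed)
  v <- seq(2, 2 + n_meta - 1)           # strictly increasing signal
  noise <- matrix(rpois(n_meta * n_noise, 5), n_meta, n_noise)
  libsize <- 10 * (max(v) + n_noise * 20)
  acc <- cbind(v, matrix(0, n_meta, 1L), noise)
  acc[, 2L] <- libsize - rowSums(acc)
  colnames(acc) <- c("pk_signal", "pk_filler",
                     sprintf("pk_bg_%03d", seq_len(n_noise)))
  acc <- cbind(acc, pk_const = rep(3, n_meta))
  acc[, "pk_filler"] <- acc[, "pk_filler"] - 3
  expr <- cbind(v, libsize - v)
  colnames(expr) <- c("g_signal", "g_filler")
  ps <- peak_set(chrom = rep("chr1", ncol(acc)),
                 start = seq(0, by = 1000, length.out = ncol(acc)),
                 end = seq(500, by = 1000, length.out = ncol(acc)),
                 id = colnames(acc),
                 gc_fraction = runif(ncol(acc), 0.4, 0.6),
                 accessibility = colMeans(acc))
  list(mc = structure(list(accessibility = acc, expression = expr,
                           k = 1L, membership = as.list(seq_len(n_meta))),
                      class = "MetacellMatrix"),
       peaks = ps)
}
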