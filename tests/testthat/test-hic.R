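test_that("Hi-C pair filters apply mapq, fragment, distance and dedup rules", {
  rec <- data.frame(
    read_id = paste0("r", 1:8),
    chromA = "chr1", posA = c(1e6, 1e6, 1e6, 1e6, 1e6, 1e6, 1e6, 2e6),
    fragA = 1:8,
    chromB = "chr1",
    posB = c(2e6, 2e6, 2e6, 1e6 + 999, 1e6 + 1000, 2e6, 2e6, 3e6),
    fragB = c(101:103, 104, 105, 6, 107, 108),
    mapqA = c(31, 30, 20, 31, 31, 31, 31, 31),
    mapqB = c(31, 31, 31, 31, 31, 31, 31, 31))
  kept <- filter_hic_pairs(rec)
  # r1 kept; r2 mapq == 30 removed (> 30 required); r3 low mapq;
  # r4 separation 999 < 1 kb removed; r5 separation exactly 1 kb kept;
  # r6 same fragment removed; r7 duplicate of r1 removed; r8 kept
  expect_setequal(kept$read_id, c("r1", "r5", "r8"))
  st <- attr(kept, "filter_stats")
  expect_equal(unname(st["duplicates"]), 1)
  expect_error(filter_hic_pairs(transform(rec, posA = NA)), "line 1")
  # binning round-trip
  cmx <- pairs_to_contact_matrix(kept, "chr1", 1e6, nbins = 4)
  expect_equal(sum(cmx$counts), 5)  # two symmetric off-diagonal + one diag
})

test_that("balancing reaches uniform row sums and preserves symmetry", {
  cfg <- sim_config(seed = 13, n_bins = 80)
  g <- gen_contact_map(cfg)
  bal <- balance_matrix(g$matrix, tol = 1e-7)
  rs <- rowSums(bal$counts, na.rm = TRUE)
  rs <- rs[rs > 0]
  expect_lt(sd(rs) / mean(rs), 1e-6)
  expect_true(isSymmetric(unname(bal$counts)))
  # a constant positive matrix is already balanced: unchanged up to scale
  const <- contact_matrix(matrix(5, 60, 60), 1e5)
  balc <- balance_matrix(const)
  expect_lt(diff(range(balc$counts / const$counts)), 1e-9)
})

test_that("distance decay normalizes to 1 and is scale-invariant", {
  cfg <- sim_config(seed = 14, n_bins = 100)
  g <- gen_contact_map(cfg)
  dd <- distance_decay(g$matrix)
  expect_equal(sum(dd$p_s), 1, tolerance = 1e-12)
  expect_true(all(dd$p_s >= 0))
  scaled <- contact_matrix(g$matrix$counts * 7.5, g$matrix$bin_size)
  expect_equal(distance_decay(scaled)$p_s, dd$p_s, tolerance = 1e-12)
  # pure power-law expectation: P(s) strictly decreasing across bins
  expect_true(all(diff(dd$mean_count) < 0))
  expect_error(distance_decay(contact_matrix(matrix(0, 60, 60), 1e5)),
               "empty")
})

test_that("compartment calls match planted labels and the strength oracle", {
  cfg <- sim_config(seed = 15, n_bins = 200, compartment_multiplier = 1.5)
  g <- gen_contact_map(cfg)
  track <- as.numeric(g$truth$compartment_labels == "A")
  cp <- compartments(g$matrix, orientation_track = track)
  agree <- mean(cp$labels == g$truth$compartment_labels, na.rm = TRUE)
  expect_gte(agree, 0.95)
  # oracle equivalence of the strength ratio (<= 300 x 300 matrices)
  ebd <- epiremod:::mean_by_distance(g$matrix$counts)
  oracle <- oracle_compartment_strength(g$matrix$counts, ebd, cp$labels,
                                        g$matrix$bin_size)
  expect_true(is.finite(cp$strength) && cp$strength > 1)
  expect_equal(cp$strength, oracle, tolerance = 1e-10)
  expect_error(compartments(contact_matrix(matrix(1, 5, 5), 1e5)),
               "10 usable bins")
})

test_that("insulation boundary calling: tie-breaks and equivariance", {
  # two minima within w bins: keep the deeper; exact tie: leftmost
  s1 <- c(0, 0, -1, 0, -0.5, 0, 0, 0)
  expect_equal(epiremod:::find_score_minima(s1, 0.2, min_sep = 4), 3)
  s2 <- c(0, -1, 0, -1, 0, 0)
  expect_equal(epiremod:::find_score_minima(s2, 0.2, min_sep = 4), 2)

  # translation equivariance on a noise-free planted matrix
  n <- 120; depth <- 500
  mk <- function(bnd) {
    d <- abs(outer(1:n, 1:n, "-"))
    e <- depth * pmax(d, 1)^-1
    tid <- findInterval(1:n, bnd)
    contact_matrix(e * ifelse(outer(tid, tid, "=="), 1.6, 1), 1e5)
  }
  b0 <- c(30, 60, 90)
  shift <- 7
  i0 <- insulation(mk(b0))
  i1 <- insulation(mk(b0 + shift))
  expect_equal(i1$boundaries, i0$boundaries + shift)
  expect_error(insulation(mk(b0), w = 40), "too short")
})

test_that("TAD aggregation recovers the planted interior enrichment", {
  cfg <- sim_config(seed = 16, tad_multiplier = 1.5)
  g <- gen_contact_map(cfg)
  tb <- g$truth$tad_boundaries
  tads <- data.frame(start = head(tb, -1) * cfg$bin_size,
                     end = (tb[-1] - 1) * cfg$bin_size)
  res <- aggregate_tads(g$matrix, tads, n_rescaled_bins = 20,
                        expected = analytic_decay(cfg))
  gsz <- 20
  interior <- res$map[(gsz + 3):(2 * gsz - 2), (gsz + 3):(2 * gsz - 2)]
  expect_equal(mean(interior, na.rm = TRUE), log2(1.5), tolerance = 0.1)
  # TADs shorter than 3 bins are skipped but counted
  tads2 <- rbind(tads, data.frame(start = 0, end = 2 * cfg$bin_size))
  res2 <- aggregate_tads(g$matrix, tads2, n_rescaled_bins = 10,
                         expected = analytic_decay(cfg))
  expect_equal(res2$n_skipped, 1L)
  expect_error(aggregate_tads(g$matrix, tads2[nrow(tads2), , drop = FALSE]),
               "no usable TADs")
})

test_that("APA equals the brute-force window oracle and excludes bad pairs", {
  cfg <- sim_config(seed = 17, loop_multiplier = 2, n_loops = 20,
                    n_bins = 150)
  g <- gen_contact_map(cfg)
  an <- g$truth$loop_anchors
  dd <- distance_decay(g$matrix)
  res <- apa(g$matrix, an, W = 10, expected = dd)
  orc <- oracle_apa(g$matrix$counts, dd$expected_by_dist, an, W = 10)
  expect_equal(res$map, orc$map, tolerance = 1e-10)
  expect_equal(res$center_enrichment, orc$center_enrichment,
               tolerance = 1e-10)
  # too-close pair is excluded from n_pairs
  res2 <- apa(g$matrix, rbind(an, c(50, 60)), W = 10, expected = dd)
  expect_equal(res2$n_pairs, nrow(an))
  expect_equal(res2$n_excluded, 1L)
  expect_error(apa(g$matrix, cbind(50, 60), W = 10), "zero usable")
})

test_that("pair scores are zero when observed equals expected and separate
           planted loops from distance-matched controls", {
  # constant-expected toy: observed == expected in the window -> score 0
  n <- 60
  e <- matrix(10, n, n)
  cmx <- contact_matrix(e, 1e4)
  sc <- pair_contact_scores(cmx, cbind(2.05e5, 4.05e5), window_bp = 1e4,
                            expected = rep(10, n))
  expect_equal(sc, 0, tolerance = 1e-12)
  expect_error(pair_contact_scores(cmx, cbind(-5e4, 4e5)), "outside")

  cfg <- sim_config(seed = 18, loop_multiplier = 2)
  g <- gen_contact_map(cfg)
  an <- g$truth$loop_anchors
  bs <- cfg$bin_size
  loops <- cbind((an[, 1] - 0.5) * bs, (an[, 2] - 0.5) * bs)
  ctrl <- loops + 5 * bs  # same separation, shifted off the anchors
  s1 <- pair_contact_scores(g$matrix, loops)
  s0 <- pair_contact_scores(g$matrix, ctrl)
  expect_gt(median(s1 - s0), 0)
  wt <- suppressWarnings(wilcox.test(s1, s0, paired = TRUE,
                                     alternative = "greater"))
  expect_lt(wt$p.value, 0.01)
})

test_that("hic statistics are invariant under a global coordinate shift", {
  cfg <- sim_config(seed = 19, n_bins = 90, compartment_multiplier = 1.5)
  g <- gen_contact_map(cfg)
  dd1 <- distance_decay(g$matrix)
  cm2 <- contact_matrix(g$matrix$counts, g$matrix$bin_size, chrom = "chr9")
  dd2 <- distance_decay(cm2)
  expect_equal(dd1$p_s, dd2$p_s)
  expect_equal(insulation(g$matrix)$score, insulation(cm2)$score)
})
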