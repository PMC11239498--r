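test_that("classify_overlap handles shared peaks and half-open boundaries", {
  a <- peak_set("chr1", 100, 200, id = "a1")
  b <- peak_set("chr1", 150, 250, id = "b1")
  res <- classify_overlap(a, b)
  expect_equal(unname(res$counts), c(0L, 0L, 1L, 1L))

  # touching intervals do not overlap under the half-open convention
  b2 <- peak_set("chr1", 200, 300, id = "b1")
  res2 <- classify_overlap(a, b2)
  expect_equal(unname(res2$counts), c(1L, 1L, 0L, 0L))
})

test_that("classify_overlap is a partition, mirrors on swap, matches oracle", {
  set.seed(101)
  for (rep in 1:5) {
    na <- sample(20:60, 1); nb <- sample(20:60, 1)
    mk <- function(n) {
      st <- sample(0:5000, n)
      peak_set(sample(c("chr1", "chr2"), n, TRUE), st,
               st + sample(50:400, n, TRUE),
               id = paste0("p", seq_len(n), "_", rep))
    }
    a <- mk(na); b <- mk(nb)
    mo <- sample(1:50, 1)
    res <- classify_overlap(a, b, min_overlap_bp = mo)
    expect_equal(nrow(res$a_specific) + nrow(res$shared_a), na)
    expect_equal(nrow(res$b_specific) + nrow(res$shared_b), nb)
    # mirror
    res_sw <- classify_overlap(b, a, min_overlap_bp = mo)
    expect_setequal(res_sw$shared_a$id, res$shared_b$id)
    expect_setequal(res_sw$b_specific$id, res$a_specific$id)
    # brute-force all-pairs oracle
    expect_setequal(res$shared_a$id, a$id[oracle_overlap_any(a, b, mo)])
    expect_setequal(res$shared_b$id, b$id[oracle_overlap_any(b, a, mo)])
  }
})

test_that("promoter/distal annotation respects the half-open window", {
  genes <- gene_annotation("g1", "chr1", 10000)
  pk <- peak_set(rep("chr1", 3), c(9500, 50000, 12000),
                 c(9700, 50500, 12100), id = c("p1", "p2", "p3"))
  lab <- annotate_promoter_distal(pk, genes, promoter_halfwidth_bp = 2000)
  expect_equal(lab, c("promoter-proximal", "promoter-distal",
                      "promoter-distal"))  # window end 12000 is exclusive
  expect_warning(
    lab0 <- annotate_promoter_distal(pk, genes[0, ], 2000),
    "empty gene annotation")
  expect_true(all(lab0 == "promoter-distal"))
})

test_that("matched background sampling respects bins, exclusions, seed", {
  set.seed(7)
  n <- 10000
  cand <- peak_set(rep("chr1", n), seq(0, by = 1000, length.out = n),
                   seq(500, by = 1000, length.out = n),
                   gc_fraction = runif(n), accessibility = runif(n))
  ref <- peak_set(rep("chr1", 300), seq(2e7, by = 1000, length.out = 300),
                  seq(2e7 + 500, by = 1000, length.out = 300),
                  id = paste0("r", 1:300),
                  gc_fraction = runif(300, 0.3, 0.7),
                  accessibility = runif(300, 0.2, 0.8))
  s1 <- sample_matched_background(cand, ref, match_on = "gc_fraction",
                                  n_bins = 10, n_per_ref = 10, seed = 5)
  s2 <- sample_matched_background(cand, ref, match_on = "gc_fraction",
                                  n_bins = 10, n_per_ref = 10, seed = 5)
  expect_identical(s1$id, s2$id)

  # every sampled peak sits within one quantile bin of its reference peak
  # (the function's own binning convention), and the aggregate sampled
  # distribution tracks the reference distribution
  edges <- quantile(cand$gc_fraction, seq(0, 1, 0.1), names = FALSE)
  to_bin <- function(x) pmin(pmax(findInterval(
    x, edges, rightmost.closed = TRUE, all.inside = TRUE), 1L), 10L)
  ref_bin <- to_bin(ref$gc_fraction)[match(s1$matched_to, ref$id)]
  expect_true(all(abs(to_bin(s1$gc_fraction) - ref_bin) <= 1))
  prop_s <- tabulate(to_bin(s1$gc_fraction), 10) / nrow(s1)
  prop_r <- tabulate(to_bin(ref$gc_fraction), 10) / nrow(ref)
  expect_lt(max(abs(prop_s - prop_r)), 0.05)

  # hard exclusion constraint
  excl <- cand[1:5000, ]; class(excl) <- class(cand)
  s3 <- sample_matched_background(cand, ref, match_on = "gc_fraction",
                                  n_bins = 10, n_per_ref = 5,
                                  exclude = excl, seed = 5)
  expect_length(intersect(s3$id, excl$id), 0)

  # single-bin references stay in their decile
  ref5 <- ref[ref$gc_fraction >= edges[5] & ref$gc_fraction < edges[6], ]
  class(ref5) <- class(ref)
  s4 <- sample_matched_background(cand, ref5, match_on = "gc_fraction",
                                  n_bins = 10, n_per_ref = 2, seed = 5)
  expect_true(all(s4$gc_fraction >= edges[5] & s4$gc_fraction < edges[6]))
})

test_that("DEG-window overlap fractions use half-open windows", {
  genes <- gene_annotation(paste0("g", 1:10), rep("chr1", 10),
                           seq(1e6, by = 1e6, length.out = 10))
  # peaks within the window of genes 1..4 only
  pk <- peak_set(rep("chr1", 4), genes$tss[1:4] + 50000,
                 genes$tss[1:4] + 50500, id = paste0("p", 1:4))
  degs <- data.frame(gene_id = genes$gene_id,
                     direction = rep("up", 10))
  res <- suppressWarnings(deg_peak_overlap_fraction(
    degs, list(cat1 = pk), genes, window_bp = 100000))
  expect_equal(res$percent[res$direction == "up"], 40.0)

  # a peak starting exactly at tss + window is outside (half-open)
  pk_edge <- peak_set("chr1", genes$tss[5] + 100000,
                      genes$tss[5] + 100500, id = "pe")
  res2 <- suppressWarnings(deg_peak_overlap_fraction(
    degs, list(edge = pk_edge), genes, window_bp = 100000))
  expect_equal(res2$percent[res2$direction == "up"], 0)

  expect_error(
    deg_peak_overlap_fraction(
      data.frame(gene_id = "g1", direction = "sideways"),
      list(cat1 = pk), genes, 1000),
    "unknown direction")
})

test_that("BED and PWM round-trips preserve content", {
  pk <- peak_set(c("chr1", "chr2"), c(0, 100), c(50, 900),
                 id = c("x", "y"), gc_fraction = c(0.5, 0.25))
  f <- tempfile(fileext = ".bed")
  write_bed(pk, f)
  back <- read_bed(f, extra_cols = "gc_fraction")
  expect_equal(back$start, pk$start)
  expect_equal(back$gc_fraction, pk$gc_fraction)

  pwm <- matrix(c(8, 1, 1, 0), 4, 5, dimnames = list(c("A","C","G","T"), NULL))
  fp <- tempfile()
  write_pwm(pwm, fp)
  expect_equal(unname(read_pwm(fp)), unname(pwm))
})
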