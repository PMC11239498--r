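test_that("cell QC keeps exactly the cells inside all bounds", {
  qc <- data.frame(
    cell_id = paste0("c", 1:12),
    genes_detected = c(999, 1000, 30000, 30001, rep(5000, 8)),
    umis = c(rep(5000, 4), 999, 1000, rep(5000, 6)),
    fragments = c(rep(20000, 6), 7999, 8000, 125000, 125001, 20000, 20000),
    tss_enrichment = c(rep(5, 10), 0.99, 5),
    nucleosome_signal = c(rep(0.5, 11), 0.19))
  kept <- filter_cells_qc(qc)
  expect_setequal(kept, c("c2", "c3", "c6", "c8", "c9"))
  expect_error(filter_cells_qc(qc[, -3]), "umis")
})

test_that("make_metacells with k = 1 is the identity up to ordering", {
  set.seed(12)
  acc <- matrix(rpois(100 * 30, 2), 100, 30,
                dimnames = list(paste0("c", 1:100), paste0("p", 1:30)))
  expr <- matrix(rpois(100 * 20, 3), 100, 20,
                 dimnames = list(paste0("c", 1:100), paste0("g", 1:20)))
  mc <- make_metacells(acc, expr, k = 1, seed = 3)
  expect_equal(nrow(mc$expression), 100)
  expect_true(all(lengths(mc$membership) == 1))
  expect_setequal(unlist(mc$membership), rownames(acc))
  ord <- match(unlist(mc$membership), rownames(acc))
  expect_equal(unname(mc$accessibility), unname(acc[ord, ]))

  # determinism and disjoint membership at k > 1
  mc5a <- make_metacells(acc, expr, k = 5, seed = 3)
  mc5b <- make_metacells(acc, expr, k = 5, seed = 3)
  expect_identical(mc5a$membership, mc5b$membership)
  expect_false(any(duplicated(unlist(mc5a$membership))))
  expect_warning(make_metacells(acc, expr, k = 500, seed = 1), "single")
})

test_that("metacell aggregation sharpens planted correlations", {
  cfg <- sim_config(seed = 21, n_cells = 1500, n_peaks = 500, n_genes = 80,
                    n_linked = 10)
  mo <- gen_multiome(cfg)
  kept <- filter_cells_qc(mo$qc)
  mc <- make_metacells(mo$atac[kept, ], mo$rna[kept, ], k = 50, seed = 21)
  tp <- mo$truth$linked_pairs
  r_mc <- vapply(seq_len(nrow(tp)), function(i)
    cor(mc$accessibility[, tp$peak_id[i]], mc$expression[, tp$gene_id[i]]),
    numeric(1))
  r_sc <- vapply(seq_len(nrow(tp)), function(i)
    cor(as.numeric(mo$atac[kept, tp$peak_id[i]]),
        as.numeric(mo$rna[kept, tp$gene_id[i]])), numeric(1))
  expect_gt(mean(r_mc), mean(r_sc))
})

test_that("candidate_pairs enforces the 5 kb - 500 kb distance window", {
  genes <- gene_annotation("g1", "chr1", 1e6)
  mkpk <- function(d) peak_set("chr1", 1e6 + d - 250, 1e6 + d + 250,
                               id = paste0("p", d))
  for (d in c(4000, 600000))
    expect_equal(nrow(candidate_pairs(mkpk(d), genes)), 0)
  for (d in c(5000, 100000, 500000)) {
    cp <- candidate_pairs(mkpk(d), genes)
    expect_equal(cp$d, d)
  }
  # different chromosome never pairs
  pk2 <- peak_set("chr2", 1e6 + 50000, 1e6 + 50500, id = "px")
  expect_equal(nrow(candidate_pairs(pk2, genes)), 0)
})

test_that("collinear pairs reach the minimum attainable empirical p", {
  toy <- make_toy_metacells()
  pairs <- data.frame(peak_id = c("pk_signal", "pk_const"),
                      gene_id = "g_signal", chrom = "chr1",
                      d = c(50000, 60000))
  links <- correlate_and_test(toy$mc, pairs, toy$peaks, n_bg = 50, seed = 2)
  expect_equal(links$r[1], 1.0, tolerance = 1e-12)
  expect_equal(links$p_emp[1], 1 / 51)
  # constant accessibility vector is untestable, r missing
  expect_identical(links$class[2], "untestable")
  expect_true(is.na(links$r[2]))
  # p_emp floor invariant
  expect_true(all(links$p_emp >= 1 / 51, na.rm = TRUE))
  expect_error(
    correlate_and_test(
      structure(list(accessibility = toy$mc$accessibility[1:2, ],
                     expression = toy$mc$expression[1:2, ], k = 1,
                     membership = list()), class = "MetacellMatrix"),
      pairs, toy$peaks, n_bg = 50),
    "fewer than 3")
})

test_that("BH adjustment matches a hand-computed table and p.adjust", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.060, 0.074, 0.205, 0.212,
         0.216)
  manual <- c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.074 * 10 / 7,
              0.216, 0.216, 0.216)
  expect_equal(bh_adjust(p), manual, tolerance = 1e-12)
  set.seed(4)
  pr <- runif(100)^2
  expect_equal(bh_adjust(pr), p.adjust(pr, "BH"), tolerance = 1e-12)
  # NA propagation
  expect_equal(bh_adjust(c(0.01, NA, 0.5))[2], NA_real_)
})

test_that("classify_links applies the r and FDR thresholds", {
  links <- data.frame(peak_id = paste0("p", 1:5), gene_id = "g",
                      chrom = "chr1", d = 5e4,
                      r = c(0.5, -0.5, 0.2, 0.5, 0.36),
                      p_emp = c(0.01, 0.01, 0.001, 0.2, 0.01),
                      q = c(0.05, 0.05, 0.001, 0.3, 0.15),
                      class = NA_character_)
  out <- classify_links(links)
  expect_equal(out$class,
               c("positive", "negative", "non-correlated",
                 "non-correlated", "non-correlated"))
  # every testable link gets exactly one class
  expect_false(any(is.na(out$class)))
})
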