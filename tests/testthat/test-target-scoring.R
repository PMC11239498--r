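mk_links <- function(peak, gene, r, class = "positive") {
  data.frame(peak_id = peak, gene_id = gene, chrom = "chr1", d = 5e4,
             r = r, p_emp = 0.01, q = 0.05, class = class,
             stringsAsFactors = FALSE)
}

test_that("gene linkage score sums r^2 over TF-evidenced links", {
  links <- mk_links(c("p1", "p2"), "g1", c(0.5, 0.6))
  tf <- c(p1 = TRUE, p2 = TRUE)
  sc <- gene_linkage_score(links, tf, c(g1 = TRUE))
  expect_equal(sc$L, 0.25 + 0.36 + 1)          # worked value 1.61
  expect_equal(sc$n_pairs, 2L)
  expect_equal(sc$n_hits, 3L)

  # no TF-bearing links, no promoter hit -> 0, gene retained
  sc0 <- gene_linkage_score(links, c(p1 = FALSE, p2 = FALSE),
                            c(g1 = FALSE))
  expect_equal(sc0$L, 0)
  # a single TF-bearing link r = 0.4
  sc1 <- gene_linkage_score(mk_links("p1", "g1", 0.4),
                            c(p1 = TRUE), c(g1 = FALSE))
  expect_equal(sc1$L, 0.16)
  # only positive links contribute
  scn <- gene_linkage_score(mk_links("p1", "g1", 0.9, class = "negative"),
                            c(p1 = TRUE), c(g1 = FALSE))
  expect_equal(scn$L, 0)
  expect_error(gene_linkage_score(mk_links("p1", "gX", 0.4),
                                  c(p1 = TRUE), c(g1 = TRUE)),
               "unknown gene")
})

test_that("linkage score is additive over disjoint link subsets and matches
           a brute-force oracle on enumerated toy links", {
  set.seed(77)
  n <- 18
  links <- mk_links(paste0("p", 1:n),
                    sample(paste0("g", 1:5), n, TRUE),
                    round(runif(n, 0.36, 0.9), 3))
  tf <- setNames(runif(n) < 0.6, paste0("p", 1:n))
  prom <- setNames(runif(5) < 0.4, paste0("g", 1:5))
  sc <- gene_linkage_score(links, tf, prom)
  # oracle: explicit per-gene loop
  for (g in names(prom)) {
    li <- links[links$gene_id == g, ]
    expected <- sum(li$r[tf[li$peak_id]]^2) + as.numeric(prom[[g]])
    expect_equal(sc$L[sc$gene_id == g], expected, tolerance = 1e-12)
  }
  # additivity over a partition of one gene's links
  g <- links$gene_id[1]
  li <- links[links$gene_id == g, ]
  half <- seq_len(floor(nrow(li) / 2))
  pr0 <- setNames(FALSE, g)
  l_whole <- gene_linkage_score(li, tf, pr0)$L
  l_parts <- gene_linkage_score(li[half, ], tf, pr0)$L +
    gene_linkage_score(li[-half, ], tf, pr0)$L
  expect_equal(l_whole, l_parts, tolerance = 1e-12)
})

test_that("hypergeometric enrichment equals exact combinatorial tails", {
  # the library tail as called by the module, against direct enumeration
  for (N in c(20, 104, 200)) for (K in c(3, 13, floor(N / 2))) {
    for (m in c(1, 4, 10)) for (x in 0:min(m, K)) {
      p_mod <- phyper(x - 1, K, N - K, m, lower.tail = FALSE)
      expect_equal(p_mod, oracle_hyper_tail(x, K, N, m), tolerance = 1e-12)
    }
  }
  # worked case: m = 4, x = 3, population 104 with K = 13
  expect_equal(phyper(2, 13, 91, 4, lower.tail = FALSE),
               oracle_hyper_tail(3, 13, 104, 4), tolerance = 1e-12)
})

test_that("gene_target_enrichment builds the stated population and flags
           low-confidence genes", {
  links <- mk_links(paste0("p", 1:4), "g1", rep(0.5, 4))
  tf <- setNames(rep(c(TRUE, FALSE), c(3, 101)), paste0("p", 1:104))
  bg <- peak_set(rep("chr1", 100), seq(0, by = 1000, length.out = 100),
                 seq(500, by = 1000, length.out = 100),
                 id = paste0("p", 5:104))
  sc <- gene_linkage_score(links, tf, c(g1 = FALSE))
  out <- gene_target_enrichment(sc, links, tf, bg, n_bg_sets = 25, seed = 3)
  # m = 4 draws, x = 3 successes, population 4 + 100, K = 3 + bg hits (0)
  expect_equal(out$p_hyper, oracle_hyper_tail(3, 3, 104, 4),
               tolerance = 1e-12)
  expect_false(out$low_confidence)

  # m = 4, x = 0 -> p = 1
  tf0 <- setNames(rep(FALSE, 104), paste0("p", 1:104))
  out0 <- gene_target_enrichment(gene_linkage_score(links, tf0,
                                                    c(g1 = FALSE)),
                                 links, tf0, bg, seed = 3)
  expect_equal(out0$p_hyper, 1)

  # m = 1 -> low confidence regardless of p
  l1 <- mk_links("p1", "g1", 0.5)
  out1 <- gene_target_enrichment(gene_linkage_score(l1, tf, c(g1 = FALSE)),
                                 l1, tf, bg, seed = 3)
  expect_true(out1$low_confidence)
  expect_error(gene_target_enrichment(sc, links, tf, bg[0, ], seed = 1),
               "empty")
})

test_that("true targets with concentrated TF evidence rank in the top decile
           by linkage score", {
  set.seed(55)
  n_genes <- 200; true_targets <- paste0("g", 1:10)
  links <- do.call(rbind, lapply(1:n_genes, function(i) {
    m <- sample(3:6, 1)
    mk_links(paste0("p", i, "_", 1:m), paste0("g", i),
             runif(m, 0.5, 0.8))
  }))
  tf <- setNames(rep(FALSE, nrow(links)), links$peak_id)
  tf[links$peak_id[links$gene_id %in% true_targets]] <- TRUE
  # sparse background evidence elsewhere
  other <- links$peak_id[!links$gene_id %in% true_targets]
  tf[sample(other, 10)] <- TRUE
  prom <- setNames(rep(FALSE, n_genes), paste0("g", 1:n_genes))
  sc <- gene_linkage_score(links, tf, prom)
  top_decile <- sc$gene_id[rank(-sc$L, ties.method = "min") <=
                             ceiling(n_genes / 10)]
  expect_gte(mean(true_targets %in% top_decile), 0.9)
})
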