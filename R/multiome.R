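# Multiome enhancer-gene linking: cell QC, metacell aggregation,
# candidate pairing, correlation with a covariate-matched empirical null,
# and FDR classification.

#' Default multiome cell QC thresholds
#'
#' Keep ranges per metric (inclusive on the keep side): genes detected in
#' [1,000, 30,000], UMIs >= 1,000, unique ATAC fragments in
#' [8,000, 125,000], TSS enrichment in [1, 20], nucleosome signal in
#' [0.2, 2]. Cells outside any range are removed.
#'
#' @return named list of c(lo, hi) keep ranges.
#' @export
qc_thresholds <- function() {
  list(genes_detected = c(1000, 30000),
       umis = c(1000, Inf),
       fragments = c(8000, 125000),
       tss_enrichment = c(1, 20),
       nucleosome_signal = c(0.2, 2))
}

#' Filter cells on QC metrics
#'
#' @param qc data.frame with `cell_id` and one column per metric in
#'   `thresholds`.
#' @param thresholds named list of c(lo, hi) keep ranges; defaults to
#'   [qc_thresholds()].
#' @return character vector of kept cell ids.
#' @export
filter_cells_qc <- function(qc, thresholds = qc_thresholds()) {
  stop_if_missing_cols(qc, c("cell_id", names(thresholds)), "QC table")
  keep <- rep(TRUE, nrow(qc))
  for (m in names(thresholds)) {
    rng <- thresholds[[m]]
    keep <- keep & qc[[m]] >= rng[1L] & qc[[m]] <= rng[2L]
  }
  qc$cell_id[keep]
}

#' Aggregate cells into metacells
#'
#' Groups cells into disjoint aggregates of up to k neighbors in an
#' embedding (farthest-point seeding, then each seed claims its k nearest
#' unassigned cells), and sums counts per aggregate. When no embedding is
#' given, one is built from the expression matrix by per-gene rank
#' transformation followed by truncated SVD. Aggregation over similar
#' cells preserves between-metacell biological variation while averaging
#' out sampling noise, so peak-gene correlations sharpen relative to
#' single cells.
#'
#' @param accessibility cell x peak count matrix (rows named by cell).
#' @param expression cell x gene count matrix, same cells.
#' @param k cells per metacell.
#' @param embedding optional cell x dim numeric matrix.
#' @param seed integer RNG seed (first farthest-point seed is random).
#' @param n_dims SVD dimensions for the default embedding.
#' @return object of class `MetacellMatrix`: list(accessibility,
#'   expression (metacell x feature), k, membership).
#' @export
make_metacells <- function(accessibility, expression, k = 50L,
                           embedding = NULL, seed = 1L, n_dims = 10L) {
  stopifnot(k >= 1L, nrow(accessibility) == nrow(expression))
  n <- nrow(expression)
  if (k > n) {
    warning("k exceeds the number of cells; returning a single metacell")
    k <- n
  }
  if (is.null(embedding)) {
    # joint rank-transformed feature space: top overdispersed features of
    # both modalities, per-feature rank over cells, then truncated SVD
    top_feats <- function(m, n_top = 200L) {
      m <- as.matrix(m)
      mu <- colMeans(m)
      disp <- apply(m, 2L, stats::var) / pmax(mu, 1e-9)
      m[, order(disp, decreasing = TRUE)[seq_len(min(n_top, ncol(m)))],
        drop = FALSE]
    }
    x <- cbind(top_feats(expression), top_feats(accessibility))
    x <- apply(x, 2L, rank, ties.method = "average")
    x <- scale(x, center = TRUE, scale = TRUE)
    x[!is.finite(x)] <- 0
    d <- min(n_dims, dim(x) - 1L)
    sv <- svd(x, nu = d, nv = 0L)
    embedding <- sv$u %*% diag(sv$d[seq_len(d)], d)
  }
  embedding <- as.matrix(embedding)
  n_meta <- max(1L, floor(n / k))
  membership <- with_seed(seed, {
    seeds <- integer(n_meta)
    seeds[1L] <- sample.int(n, 1L)
    mind <- colSums((t(embedding) - embedding[seeds[1L], ])^2)
    if (n_meta > 1L) for (s in 2:n_meta) {
      seeds[s] <- which.max(mind)
      mind <- pmin(mind, colSums((t(embedding) - embedding[seeds[s], ])^2))
    }
    assigned <- rep(FALSE, n)
    lapply(seq_len(n_meta), function(s) {
      d2 <- colSums((t(embedding) - embedding[seeds[s], ])^2)
      d2[assigned] <- Inf
      take <- order(d2)[seq_len(min(k, sum(!assigned)))]
      assigned[take] <<- TRUE
      sort(take)
    })
  })
  ind <- Matrix::sparseMatrix(
    i = rep(seq_along(membership), lengths(membership)),
    j = unlist(membership), x = 1,
    dims = c(length(membership), n))
  mc_names <- sprintf("mc_%04d", seq_along(membership))
  acc <- as.matrix(ind %*% accessibility)
  expr <- as.matrix(ind %*% expression)
  rownames(acc) <- rownames(expr) <- mc_names
  cells <- rownames(expression) %||% as.character(seq_len(n))
  structure(list(accessibility = acc, expression = expr, k = k,
                 membership = lapply(membership, function(ix) cells[ix])),
            class = "MetacellMatrix")
}

#' Candidate enhancer-gene pairs by distance
#'
#' All same-chromosome peak-gene pairs whose peak-center-to-TSS distance d
#' satisfies min_d <= d <= max_d (defaults: at least 5 kb, at most
#' 500 kb).
#'
#' @param peaks a `PeakSet`.
#' @param genes a `GeneAnnotation`.
#' @param min_d,max_d distance bounds in bp (inclusive).
#' @return data.frame(peak_id, gene_id, chrom, d).
#' @export
candidate_pairs <- function(peaks, genes, min_d = 5000, max_d = 500000) {
  out <- vector("list", nrow(genes))
  center <- floor((peaks$start + peaks$end) / 2)
  for (g in seq_len(nrow(genes))) {
    sel <- peaks$chrom == genes$chrom[g]
    d <- abs(center[sel] - genes$tss[g])
    ok <- d >= min_d & d <= max_d
    if (any(ok))
      out[[g]] <- data.frame(peak_id = peaks$id[sel][ok],
                             gene_id = genes$gene_id[g],
                             chrom = genes$chrom[g], d = d[ok],
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res))
    res <- data.frame(peak_id = character(), gene_id = character(),
                      chrom = character(), d = numeric())
  rownames(res) <- NULL
  res
}

# counts-per-10k + log1p, rows = metacells.
normalize_cp10k <- function(m) {
  m <- as.matrix(m)
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  log1p(m / rs * 1e4)
}

#' Correlate candidate pairs and attach an empirical null
#'
#' Pearson correlation r of log-normalized (counts-per-10k, log1p)
#' metacell accessibility versus expression for each candidate pair. The
#' null for a pair is the correlation of `n_bg` GC- and
#' accessibility-matched background peaks against the same gene; the
#' two-sided empirical p is (1 + #{|r_null| >= |r|}) / (n_valid + 1), and q
#' is Benjamini-Hochberg across all tested pairs. Pairs with a
#' zero-variance accessibility or expression vector are returned with
#' class "untestable" and excluded from the FDR denominator.
#'
#' @param metacells a `MetacellMatrix`.
#' @param pairs data.frame from [candidate_pairs()].
#' @param background_candidates `PeakSet` carrying `gc_fraction` and
#'   `accessibility`, used as the matched null pool (peaks appearing in
#'   `pairs` are excluded from it automatically).
#' @param n_bg background peaks per tested pair (>= 50).
#' @param seed integer RNG seed for background sampling.
#' @param match_on covariates to match the null on.
#' @return data.frame of class `EGPLink`: pairs with r, p_emp, q, class.
#' @export
correlate_and_test <- function(metacells, pairs, background_candidates,
                               n_bg = 100L, seed = 1L,
                               match_on = c("gc_fraction", "accessibility")) {
  stopifnot(inherits(metacells, "MetacellMatrix"), n_bg >= 50L)
  nm <- nrow(metacells$expression)
  if (nm < 3L) stop("correlation undefined with fewer than 3 metacells")
  acc <- normalize_cp10k(metacells$accessibility)
  expr <- normalize_cp10k(metacells$expression)

  zscore <- function(m) {
    mu <- colMeans(m)
    sd_ <- apply(m, 2L, stats::sd)
    list(z = sweep(sweep(m, 2L, mu), 2L, ifelse(sd_ > 0, sd_, 1), "/"),
         sd = sd_)
  }
  za <- zscore(acc); ze <- zscore(expr)

  # matched background pool: candidates never overlapping tested peaks
  tested_peaks <- unique(pairs$peak_id)
  pool <- background_candidates[
    !background_candidates$id %in% tested_peaks, , drop = FALSE]
  class(pool) <- c("PeakSet", "data.frame")
  ref <- background_candidates[
    match(tested_peaks, background_candidates$id), , drop = FALSE]
  if (anyNA(ref$id))
    stop("background_candidates must contain the tested peaks (for ",
         "covariate lookup)")
  class(ref) <- c("PeakSet", "data.frame")
  bg <- sample_matched_background(pool, ref, match_on = match_on,
                                  n_per_ref = n_bg, seed = seed)
  bg_ids <- split(bg$id, rep(seq_len(nrow(ref)), each = n_bg))
  names(bg_ids) <- tested_peaks

  r <- p_emp <- rep(NA_real_, nrow(pairs))
  cls <- rep(NA_character_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    pk <- pairs$peak_id[i]; gn <- pairs$gene_id[i]
    if (za$sd[pk] == 0 || ze$sd[gn] == 0) { cls[i] <- "untestable"; next }
    zg <- ze$z[, gn]
    r[i] <- sum(za$z[, pk] * zg) / (nm - 1L)
    rb <- as.vector(crossprod(za$z[, bg_ids[[pk]], drop = FALSE], zg)) /
      (nm - 1L)
    rb <- rb[za$sd[bg_ids[[pk]]] > 0]
    p_emp[i] <- (1 + sum(abs(rb) >= abs(r[i]))) / (length(rb) + 1L)
  }
  out <- pairs
  out$r <- r
  out$p_emp <- p_emp
  out$q <- bh_adjust(p_emp)
  out$class <- cls
  class(out) <- c("EGPLink", "data.frame")
  out
}

#' Classify enhancer-gene links
#'
#' Positively correlated: r > `r_pos` and q < `q_max`; negatively
#' correlated: r < `r_neg` and q < `q_max`; everything else tested is
#' non-correlated. Untestable links keep their label.
#'
#' @param links output of [correlate_and_test()].
#' @param r_pos,r_neg correlation thresholds (defaults 0.35 / -0.35).
#' @param q_max FDR threshold (default 0.1).
#' @return `links` with the `class` column filled.
#' @export
classify_links <- function(links, r_pos = 0.35, r_neg = -0.35, q_max = 0.1) {
  testable <- is.na(links$class) | links$class != "untestable"
  cl <- links$class
  cl[testable] <- "non-correlated"
  cl[testable & links$r > r_pos & links$q < q_max] <- "positive"
  cl[testable & links$r < r_neg & links$q < q_max] <- "negative"
  links$class <- cl
  links
}

#' Write enhancer-gene links as TSV / arcs
#'
#' `write_egp_links` writes the full link table; `write_egp_arcs` writes a
#' BEDPE-like file (peak interval, TSS interval, link id, r) for browser
#' display.
#'
#' @param links classified `EGPLink` table.
#' @param peaks,genes the objects the links refer to.
#' @param file output path.
#' @export
write_egp_links <- function(links, file) {
  utils::write.table(as.data.frame(links), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_egp_links
#' @export
write_egp_arcs <- function(links, peaks, genes, file) {
  pi_ <- match(links$peak_id, peaks$id)
  gi <- match(links$gene_id, genes$gene_id)
  bedpe <- data.frame(
    chrom1 = peaks$chrom[pi_], start1 = peaks$start[pi_],
    end1 = peaks$end[pi_],
    chrom2 = genes$chrom[gi], start2 = pmax(0, genes$tss[gi] - 1),
    end2 = genes$tss[gi] + 1,
    name = paste(links$peak_id, links$gene_id, sep = "|"),
    score = links$r)
  utils::write.table(bedpe, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}
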