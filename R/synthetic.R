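# Seeded synthetic-data generators with planted ground truth.
#
# Every generator consumes a single SimConfig and derives all randomness
# from config$seed, so identical configs give bit-identical outputs. The
# planted structures (A/B checkerboard, TADs, loop anchors, linked
# peak-gene pairs, hypomethylated dips) are returned alongside the data as
# a truth object, which is the acceptance surface for the downstream
# statistics.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic world in one validated list.
#' Defaults describe a 20-Mb chromosome binned at 100 kb, a multiome of
#' 1,000 cells x 2,000 peaks x 200 genes with 50 planted enhancer-gene
#' links at rho = 0.7, and a methylome with baseline 0.8 dipping to 0.3 at
#' feature centers under 30x Poisson coverage.
#'
#' @param seed integer master seed; all generator randomness flows from it.
#' @param n_bins,bin_size contact-map bins and bin width (bp).
#' @param decay_exponent power-law exponent alpha of contact decay.
#' @param contact_depth expected contacts at 1-bin separation.
#' @param compartment_multiplier checkerboard multiplier c >= 1 (same-label
#'   pairs x c, different-label pairs / c).
#' @param compartment_block_bins bins per alternating A/B block.
#' @param tad_multiplier intra-TAD multiplier f >= 1.
#' @param n_tad_boundaries planted TAD boundaries.
#' @param loop_multiplier loop-anchor multiplier l >= 1 at patch center.
#' @param n_loops planted loop anchor pairs.
#' @param loop_sigma Gaussian width (bins) of the 3x3 loop patch.
#' @param n_cells,n_peaks,n_genes multiome dimensions (QC-passing cells).
#' @param n_linked planted peak-gene links.
#' @param rho planted aggregate-level Pearson correlation, in [-1, 1].
#' @param gene_depth,peak_depth mean per-cell counts of planted features.
#' @param qc_fail_frac fraction of extra cells emitted with a QC metric
#'   planted outside the keep range.
#' @param tf_bound_frac_linked,tf_bound_frac_other probability that a
#'   linked / other peak carries TF binding evidence.
#' @param promoter_tf_frac probability of TF evidence at a gene promoter.
#' @param m0,m1 methylation baseline and dip level, 0 <= m1 <= m0 <= 1.
#' @param coverage_rate Poisson mean of per-CpG total coverage (lambda).
#' @param n_meth_features,meth_feature_width_bp,dip_sigma_bp,cpg_spacing_bp
#'   methylome feature layout.
#' @param low_coverage_frac,non_cpg_frac fractions of CpG sites planted
#'   with coverage < 10 / with non-CpG context, to exercise filters.
#' @param n_a_specific,n_b_specific,n_shared ChIP peak-universe counts.
#' @param motif_consensus consensus of the planted motif (default the
#'   E-box CAGATG bound by proneural bHLH factors).
#' @param max_motif_copies maximum planted copies per peak.
#' @param peak_seq_length length of emitted peak sequences (bp).
#' @return validated list of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       n_bins = 200L, bin_size = 100000L,
                       decay_exponent = 1.0, contact_depth = 500,
                       compartment_multiplier = 1.0,
                       compartment_block_bins = 20L,
                       tad_multiplier = 1.0, n_tad_boundaries = 10L,
                       loop_multiplier = 1.0, n_loops = 50L,
                       loop_sigma = 2.0,
                       n_cells = 1000L, n_peaks = 2000L, n_genes = 200L,
                       n_linked = 50L, rho = 0.7,
                       gene_depth = 5, peak_depth = 5,
                       qc_fail_frac = 0.05,
                       tf_bound_frac_linked = 0.8,
                       tf_bound_frac_other = 0.05,
                       promoter_tf_frac = 0.3,
                       m0 = 0.8, m1 = 0.3, coverage_rate = 30,
                       n_meth_features = 100L,
                       meth_feature_width_bp = 300L,
                       dip_sigma_bp = 150, cpg_spacing_bp = 25L,
                       low_coverage_frac = 0.05, non_cpg_frac = 0.05,
                       n_a_specific = 10L, n_b_specific = 10L,
                       n_shared = 30L,
                       motif_consensus = "CAGATG",
                       max_motif_copies = 3L,
                       peak_seq_length = 200L) {
  cfg <- as.list(environment())
  if (cfg$decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (cfg$n_bins < 1L) stop("n_bins must be positive")
  if (cfg$bin_size <= 0) stop("bin_size must be positive")
  for (m in c("compartment_multiplier", "tad_multiplier", "loop_multiplier"))
    if (cfg[[m]] < 1) stop(m, " must be >= 1")
  if (cfg$rho < -1 || cfg$rho > 1) stop("rho must lie in [-1, 1]")
  if (!(cfg$m1 >= 0 && cfg$m1 <= cfg$m0 && cfg$m0 <= 1))
    stop("need 0 <= m1 <= m0 <= 1")
  if (cfg$coverage_rate <= 0) stop("coverage_rate (lambda) must be > 0")
  for (m in c("contact_depth", "n_cells", "n_peaks", "n_genes",
              "gene_depth", "peak_depth"))
    if (cfg[[m]] <= 0) stop(m, " must be positive")
  if (cfg$n_linked > min(cfg$n_peaks, cfg$n_genes))
    stop("n_linked cannot exceed n_peaks or n_genes")
  class(cfg) <- c("SimConfig", "list")
  cfg
}

#' Simulate a binned Hi-C contact map with planted structure
#'
#' Expected counts follow a power law in genomic distance,
#' E[i,j] = depth * |i-j|^(-alpha), modulated by an alternating-block A/B
#' checkerboard (x c for same-label pairs, / c otherwise), an intra-TAD
#' boost f, and 3x3 Gaussian loop patches of peak multiplier l at planted
#' anchor pairs. Observed counts are Poisson draws, symmetrized.
#'
#' @param config a [sim_config()].
#' @return list(matrix = `ContactMatrix`, truth) where truth carries
#'   `compartment_labels` (per bin, "A"/"B"), `tad_boundaries` (1-based bin
#'   indices), `loop_anchors` (2-column bin-index matrix) and the seed.
#' @export
gen_contact_map <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_bins < 50L) stop("need n_bins >= 50 for a usable contact map")
  n <- config$n_bins
  with_seed(config$seed, {
    # planted labels: alternating A/B blocks
    blk <- config$compartment_block_bins
    labels <- rep(rep(c("A", "B"), length.out = ceiling(n / blk)),
                  each = blk)[seq_len(n)]
    # planted TAD boundaries: quasi-even with +-2 bin jitter
    nb <- config$n_tad_boundaries
    boundaries <- integer(0)
    if (nb > 0L) {
      base <- round(seq(1, n + 1, length.out = nb + 2L))[2:(nb + 1L)]
      boundaries <- base + sample(-2:2, nb, replace = TRUE)
      boundaries <- sort(unique(pmin(pmax(boundaries, 5L), n - 4L)))
    }
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    e <- config$contact_depth * pmax(d, 1L)^(-config$decay_exponent)
    if (config$compartment_multiplier > 1) {
      same <- outer(labels, labels, "==")
      e <- e * ifelse(same, config$compartment_multiplier,
                      1 / config$compartment_multiplier)
    }
    if (config$tad_multiplier > 1 && length(boundaries) > 0L) {
      tid <- findInterval(seq_len(n), boundaries)
      e <- e * ifelse(outer(tid, tid, "=="), config$tad_multiplier, 1)
    }
    # planted loop anchors, separated by more than the APA window extent
    anchors <- NULL
    if (config$loop_multiplier > 1 && config$n_loops > 0L) {
      w_guard <- 12L
      min_sep <- 25L
      max_sep <- min(80L, n - 2L * w_guard - 2L)
      if (max_sep < min_sep) stop("chromosome too short to plant loops")
      a1 <- sample(seq(w_guard + 1L, n - w_guard - min_sep), config$n_loops,
                   replace = TRUE)
      sep <- sample(seq(min_sep, max_sep), config$n_loops, replace = TRUE)
      a2 <- pmin(a1 + sep, n - w_guard)
      anchors <- cbind(a1, a2)
      lmul <- config$loop_multiplier
      for (k in seq_len(nrow(anchors))) {
        ii <- anchors[k, 1L] + (-1:1); jj <- anchors[k, 2L] + (-1:1)
        g <- exp(-outer((-1:1)^2, (-1:1)^2, "+") / (2 * config$loop_sigma^2))
        e[ii, jj] <- e[ii, jj] * (1 + (lmul - 1) * g)
        e[jj, ii] <- e[jj, ii] * (1 + (lmul - 1) * t(g))
      }
    }
    # Poisson draw on the upper triangle, mirrored
    m <- matrix(0, n, n)
    ut <- upper.tri(m, diag = TRUE)
    m[ut] <- stats::rpois(sum(ut), e[ut])
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    truth <- structure(list(compartment_labels = labels,
                            tad_boundaries = boundaries,
                            loop_anchors = anchors,
                            seed = config$seed),
                       class = c("SimTruth", "list"))
    list(matrix = contact_matrix(m, bin_size = config$bin_size,
                                 chrom = "chr1"),
         truth = truth)
  })
}

#' Simulate a paired single-cell multiome with planted enhancer-gene links
#'
#' Each cell carries a latent 2-D state (u1, u2) ~ U(0,1)^2 mimicking a
#' maturation axis. Planted genes respond to u1; the planted peak of each
#' link responds to rho * u1 + sqrt(1 - rho^2) * u2, so the population
#' correlation between the two rates is exactly rho and survives metacell
#' aggregation. All other peaks and genes are feature-specific Poisson
#' noise, independent of the latent state. The genomic layout places each
#' planted link in its own locus (TSS spacing 1.2 Mb, peak 50 kb from the
#' TSS) with a small number of unlinked peaks near unlinked genes and the
#' rest in gene-free deserts, yielding a candidate-pair universe in which
#' planted links are a realistic minority (~15%).
#'
#' An extra `qc_fail_frac` of cells is emitted with one QC metric planted
#' outside the keep range so QC filtering is exercised end to end.
#'
#' @param config a [sim_config()].
#' @return list with sparse `atac` (cell x peak) and `rna` (cell x gene)
#'   count matrices, `qc` per-cell table, `peaks` (`PeakSet` with
#'   gc_fraction, accessibility, tf_bound), `genes` (`GeneAnnotation` plus
#'   `promoter_tf`), and `truth` with `linked_pairs`.
#' @export
gen_multiome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_cells < 100L) stop("need n_cells >= 100")
  with_seed(config$seed, {
    n_pass <- config$n_cells
    n_fail <- round(config$qc_fail_frac * n_pass)
    n_all <- n_pass + n_fail
    nl <- config$n_linked
    ng <- config$n_genes
    np <- config$n_peaks
    rho <- config$rho

    u1 <- stats::runif(n_all); u2 <- stats::runif(n_all)

    # ---- genomic layout -------------------------------------------------
    gene_ids <- sprintf("gene_%04d", seq_len(ng))
    tss <- 1e6 + (seq_len(ng) - 1L) * 1.2e6
    peak_w <- 500
    pk_chrom <- character(np); pk_start <- numeric(np)
    pk_start[seq_len(nl)] <- tss[seq_len(nl)] + 50000          # planted
    n_near <- min(2L * (ng - nl), np - nl)
    if (n_near > 0L) {                                         # near-null
      host <- rep(seq(nl + 1L, ng), length.out = n_near)
      off <- sample(c(-1, 1), n_near, TRUE) *
        stats::runif(n_near, 100000, 400000)
      pk_start[nl + seq_len(n_near)] <- pmax(0, tss[host] + off)
    }
    n_desert <- np - nl - n_near
    if (n_desert > 0L) {                                       # gene-free
      desert0 <- max(tss) + 2e6
      pk_start[nl + n_near + seq_len(n_desert)] <-
        desert0 + (seq_len(n_desert) - 1L) * 5000
    }
    peak_ids <- sprintf("peak_%05d", seq_len(np))

    # ---- rates ----------------------------------------------------------
    # Alternate the sign of the planted response (up- and down-regulated
    # programs along the maturation axis). Balanced signs keep library
    # sizes independent of the latent state, so normalization does not
    # induce spurious correlations between unlinked features.
    sgn <- rep_len(c(1, -1), nl)
    lam_rna <- matrix(0, n_all, ng)
    if (nl > 0L)
      lam_rna[, seq_len(nl)] <- config$gene_depth *
        (0.1 + 0.9 * (0.5 + outer(u1 - 0.5, sgn)))
    if (ng > nl) {
      base_g <- exp(stats::rnorm(ng - nl, 0, 0.5)) * config$gene_depth * 0.5
      lam_rna[, seq(nl + 1L, ng)] <- rep(base_g, each = n_all)
    }
    tlat <- rho * (u1 - 0.5) + sqrt(1 - rho^2) * (u2 - 0.5)
    lam_atac <- matrix(0, n_all, np)
    if (nl > 0L) {
      wlat <- pmin(pmax(0.5 + outer(tlat, sgn), 0), 1)
      lam_atac[, seq_len(nl)] <- config$peak_depth * (0.1 + 0.9 * wlat)
    }
    if (np > nl) {
      base_p <- exp(stats::rnorm(np - nl, -0.85, 0.5))
      lam_atac[, seq(nl + 1L, np)] <- rep(base_p, each = n_all)
    }
    rna <- matrix(stats::rpois(length(lam_rna), lam_rna), n_all, ng,
                  dimnames = list(sprintf("cell_%05d", seq_len(n_all)),
                                  gene_ids))
    atac <- matrix(stats::rpois(length(lam_atac), lam_atac), n_all, np,
                   dimnames = list(rownames(rna), peak_ids))

    # ---- QC table: pass cells inside all bounds, fail cells planted out -
    qc <- data.frame(
      cell_id = rownames(rna),
      genes_detected = round(stats::runif(n_all, 2000, 15000)),
      umis = round(stats::runif(n_all, 5000, 50000)),
      fragments = round(stats::runif(n_all, 10000, 100000)),
      tss_enrichment = stats::runif(n_all, 2, 15),
      nucleosome_signal = stats::runif(n_all, 0.3, 1.5),
      stringsAsFactors = FALSE)
    if (n_fail > 0L) {
      idx <- n_pass + seq_len(n_fail)
      mode <- rep_len(1:8, n_fail)
      qc$genes_detected[idx][mode == 1L] <- 900
      qc$genes_detected[idx][mode == 2L] <- 31000
      qc$umis[idx][mode == 3L] <- 500
      qc$fragments[idx][mode == 4L] <- 7000
      qc$fragments[idx][mode == 5L] <- 130000
      qc$tss_enrichment[idx][mode == 6L] <- 0.5
      qc$nucleosome_signal[idx][mode == 7L] <- 0.1
      qc$nucleosome_signal[idx][mode == 8L] <- 2.5
    }

    tf_bound <- c(
      stats::rbinom(nl, 1L, config$tf_bound_frac_linked) == 1L,
      stats::rbinom(np - nl, 1L, config$tf_bound_frac_other) == 1L)
    peaks <- peak_set(chrom = rep("chr1", np), start = pk_start,
                      end = pk_start + peak_w, id = peak_ids,
                      gc_fraction = stats::runif(np, 0.35, 0.65),
                      accessibility = colMeans(atac[seq_len(n_pass), ,
                                                    drop = FALSE]),
                      tf_bound = tf_bound)
    genes <- gene_annotation(gene_ids, rep("chr1", ng), tss)
    genes$promoter_tf <- stats::rbinom(ng, 1L, config$promoter_tf_frac) == 1L

    truth <- structure(list(
      linked_pairs = data.frame(peak_id = peak_ids[seq_len(nl)],
                                gene_id = gene_ids[seq_len(nl)],
                                rho = rep(rho, nl), stringsAsFactors = FALSE),
      seed = config$seed), class = c("SimTruth", "list"))
    list(atac = methods::as(Matrix::Matrix(atac, sparse = TRUE), "CsparseMatrix"),
         rna = methods::as(Matrix::Matrix(rna, sparse = TRUE), "CsparseMatrix"),
         qc = qc, peaks = peaks, genes = genes, truth = truth)
  })
}

#' Simulate a CpG methylation track with planted hypomethylated dips
#'
#' CpG sites sit on a regular grid; the true methylation level is `m0`
#' baseline with smooth Gaussian dips to `m1` at feature centers. Total
#' coverage is Poisson(lambda) and methylated counts are Binomial(total,
#' level). A configurable fraction of sites is emitted with coverage < 10
#' and a fraction flagged non-CpG, to exercise the filters.
#'
#' @param config a [sim_config()].
#' @return list(track = `MethylationTrack` data.frame, truth) where truth
#'   carries `hypomethylated_features` (0-based half-open intervals), `m0`,
#'   `m1`, `dip_sigma_bp`.
#' @export
gen_methylome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    nf <- config$n_meth_features
    fw <- config$meth_feature_width_bp
    spacing <- 10000
    f_start <- 5000 + (seq_len(nf) - 1L) * spacing
    centers <- f_start + fw / 2
    pos <- seq(0, max(f_start) + fw + 5000, by = config$cpg_spacing_bp)
    # distance to nearest feature center (centers are sorted)
    ix <- findInterval(pos, centers)
    d_lo <- abs(pos - centers[pmax(ix, 1L)])
    d_hi <- abs(pos - centers[pmin(ix + 1L, nf)])
    dmin <- pmin(d_lo, d_hi)
    level <- config$m0 - (config$m0 - config$m1) *
      exp(-dmin^2 / (2 * config$dip_sigma_bp^2))
    n <- length(pos)
    total <- stats::rpois(n, config$coverage_rate)
    lowc <- stats::runif(n) < config$low_coverage_frac
    total[lowc] <- pmin(stats::rpois(sum(lowc), 3), 9L)
    context <- ifelse(stats::runif(n) < config$non_cpg_frac, "CHH", "CpG")
    meth <- stats::rbinom(n, total, level)
    track <- methylation_track(chrom = rep("chr1", n), pos = pos,
                               context = context, meth = meth, total = total)
    truth <- structure(list(
      hypomethylated_features = data.frame(chrom = "chr1", start = f_start,
                                           end = f_start + fw),
      m0 = config$m0, m1 = config$m1,
      dip_sigma_bp = config$dip_sigma_bp,
      seed = config$seed), class = c("SimTruth", "list"))
    list(track = track, truth = truth)
  })
}

random_seq <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
}

# Remove all motif matches from a sequence by mutating hit centers.
scrub_motif <- function(seq, smat, thr) {
  w <- ncol(smat)
  for (iter in 1:50) {
    h <- scan_hits(seq, smat, thr)
    if (nrow(h) == 0L) return(seq)
    ch <- strsplit(seq, "")[[1]]
    at <- h$start[1L] + floor(w / 2)
    ch[at] <- sample(setdiff(DNA_BASES, ch[at]), 1L)
    seq <- paste(ch, collapse = "")
  }
  stop("failed to scrub motif hits from a synthetic sequence")
}

#' Simulate a two-condition ChIP peak universe with planted motifs
#'
#' Emits two peak sets with controlled numbers of condition-specific and
#' shared peaks (shared peaks have identical coordinates in both sets),
#' plus per-peak sequences carrying an exact planted number of motif
#' copies (forward or reverse strand), per-peak GC content and
#' accessibility scalars.
#'
#' @param config a [sim_config()].
#' @return list(peaks_a, peaks_b (`PeakSet`s with `motif_count` = planted
#'   copies), sequences (named by peak id), motif (consensus), truth).
#' @export
gen_chip_universe <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    na <- config$n_a_specific; nb <- config$n_b_specific
    ns <- config$n_shared
    len <- config$peak_seq_length
    motif <- config$motif_consensus
    smat <- motif_score_matrix(motif)
    thr <- 0.8 * sum(apply(smat[1:4, , drop = FALSE], 2L, max))
    w <- nchar(motif)

    n_loci <- na + nb + ns
    starts <- 10000 + (seq_len(n_loci) - 1L) * 10000
    kind <- c(rep("a", na), rep("b", nb), rep("shared", ns))
    copies <- sample(0:config$max_motif_copies, n_loci, replace = TRUE)
    gc <- stats::runif(n_loci, 0.4, 0.6)

    seqs <- character(n_loci)
    for (i in seq_len(n_loci)) {
      for (try in 1:20) {
        s <- scrub_motif(random_seq(len, gc[i]), smat, thr)
        if (copies[i] > 0L) {
          # non-overlapping slots, forward or reverse-complement
          slot <- floor(len / copies[i])
          if (slot < w + 2L) stop("peak_seq_length too short for planted copies")
          ch <- strsplit(s, "")[[1]]
          for (k in seq_len(copies[i])) {
            at <- (k - 1L) * slot + sample.int(slot - w, 1L)
            ins <- if (stats::runif(1) < 0.5) motif else
              reverse_complement(motif)
            ch[at:(at + w - 1L)] <- strsplit(ins, "")[[1]]
          }
          s <- paste(ch, collapse = "")
        }
        if (unname(count_motif_hits(s, motif)) == copies[i]) break
        if (try == 20L) stop("could not plant exact motif copy count")
      }
      seqs[i] <- s
    }
    gc_actual <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]; mean(ch %in% c("G", "C"))
    }, numeric(1L), USE.NAMES = FALSE)
    acc <- stats::runif(n_loci, 0.5, 5)

    mk <- function(sel, prefix) {
      peak_set(chrom = rep("chr1", length(sel)), start = starts[sel],
               end = starts[sel] + len,
               id = sprintf("%s_%03d", prefix, seq_along(sel)),
               gc_fraction = gc_actual[sel], accessibility = acc[sel],
               motif_count = copies[sel])
    }
    sel_a <- which(kind %in% c("a", "shared"))
    sel_b <- which(kind %in% c("b", "shared"))
    peaks_a <- mk(sel_a, "condA")
    peaks_b <- mk(sel_b, "condB")
    sequences <- c(stats::setNames(seqs[sel_a], peaks_a$id),
                   stats::setNames(seqs[sel_b], peaks_b$id))
    truth <- structure(list(
      n_a_specific = na, n_b_specific = nb, n_shared = ns,
      planted_copies = stats::setNames(copies, NULL),
      seed = config$seed), class = c("SimTruth", "list"))
    list(peaks_a = peaks_a, peaks_b = peaks_b, sequences = sequences,
         motif = motif, truth = truth)
  })
}
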