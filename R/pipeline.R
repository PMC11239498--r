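# End-to-end orchestration from a single declarative config: synthetic
# inputs -> QC/metacells -> EGP links -> target scores; contact map ->
# Hi-C statistics; methylome -> aggregation. Every stage writes plain-text
# tables plus a JSON manifest recording the config hash and seed, so
# identical config + seed reproduce identical outputs.

#' Build a run configuration
#'
#' @param outdir output directory (created if absent).
#' @param seed integer master seed, forwarded to every stage.
#' @param stages subset of c("simulate", "link", "score", "hic",
#'   "methyl") in any order; dependencies are resolved internally.
#' @param sim named list of overrides for [sim_config()].
#' @param link named list: n_bg, k (metacells), min_d, max_d.
#' @param score named list: n_bg_sets, min_pairs.
#' @param hic named list: insulation_w, min_prominence, apa_W.
#' @param methyl named list: min_total, flank_bp, n_bins.
#' @return validated list of class `RunConfig`.
#' @export
run_config <- function(outdir, seed = 1L,
                       stages = c("simulate", "link", "score", "hic",
                                  "methyl"),
                       sim = list(), link = list(), score = list(),
                       hic = list(), methyl = list()) {
  known <- c("simulate", "link", "score", "hic", "methyl")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  check_keys <- function(lst, keys, what) {
    extra <- setdiff(names(lst), keys)
    if (length(extra) > 0L)
      stop("unknown key(s) in ", what, ": ", paste(extra, collapse = ", "))
    lst
  }
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), stages = stages,
    sim = check_keys(sim, names(formals(sim_config)), "sim"),
    link = check_keys(link, c("n_bg", "k", "min_d", "max_d"), "link"),
    score = check_keys(score, c("n_bg_sets", "min_pairs"), "score"),
    hic = check_keys(hic, c("insulation_w", "min_prominence", "apa_W"),
                     "hic"),
    methyl = check_keys(methyl, c("min_total", "flank_bp", "n_bins"),
                        "methyl"))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read/write a run configuration as JSON
#' @param file path; `config` a `RunConfig`.
#' @return `read_run_config`: a validated `RunConfig`.
#' @export
write_run_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(run_config, x)
}

# Hash of the scientific configuration; the output location is excluded so
# reruns into different directories compare equal.
config_hash <- function(config) {
  x <- unclass(config)
  x$outdir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> link -> score; simulate -> hic; simulate -> methyl),
#' writing each stage's tables under `config$outdir` and a
#' `manifest.json` recording the config hash, seed, package version and
#' per-file md5 checksums.
#'
#' @param config a `RunConfig` or path to its JSON serialization.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  files <- character(0)
  emit <- function(f) files <<- c(files, f)

  need <- function(s) s %in% config$stages
  if ((need("link") || need("score") || need("hic") || need("methyl")) &&
      !need("simulate"))
    stop("stages link/score/hic/methyl require the simulate stage ",
         "(external-input mode is not wired into the orchestrator)")

  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))

  sim <- NULL
  if (need("simulate")) {
    log_msg("simulate", "generating synthetic inputs (seed ", config$seed, ")")
    sim <- list(multiome = gen_multiome(scfg),
                contacts = gen_contact_map(scfg),
                methylome = gen_methylome(scfg))
    emit(write_bed(sim$multiome$peaks, out("peaks.bed")))
    utils::write.table(sim$multiome$qc, out("cell_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("cell_qc.tsv"))
    write_triplet_matrix(sim$multiome$atac, out("atac"))
    emit(paste0(out("atac"), c(".mtx", ".rows", ".cols")))
    write_triplet_matrix(sim$multiome$rna, out("rna"))
    emit(paste0(out("rna"), c(".mtx", ".rows", ".cols")))
    emit(write_contact_matrix(sim$contacts$matrix, out("contacts.coo")))
    emit(write_methylation_track(sim$methylome$track, out("methylome.tsv")))
    jsonlite::write_json(list(multiome = unclass(sim$multiome$truth),
                              contacts = unclass(sim$contacts$truth),
                              methylome = unclass(sim$methylome$truth)),
                         out("truth.json"), auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    emit(out("truth.json"))
  }

  links <- NULL
  if (need("link") || need("score")) {
    log_msg("link", "QC filtering, metacells and EGP linking")
    mo <- sim$multiome
    kept <- filter_cells_qc(mo$qc)
    k <- config$link$k %||% 50L
    mc <- make_metacells(mo$atac[kept, , drop = FALSE],
                         mo$rna[kept, , drop = FALSE],
                         k = k, seed = config$seed)
    prs <- candidate_pairs(mo$peaks, mo$genes,
                           min_d = config$link$min_d %||% 5000,
                           max_d = config$link$max_d %||% 500000)
    links <- correlate_and_test(mc, prs, mo$peaks,
                                n_bg = config$link$n_bg %||% 100L,
                                seed = config$seed)
    links <- classify_links(links)
    emit(write_egp_links(links, out("egp_links.tsv")))
    emit(write_egp_arcs(links, mo$peaks, mo$genes, out("egp_arcs.bedpe")))
  }

  if (need("score")) {
    log_msg("score", "gene linkage scores and TF-target enrichment")
    mo <- sim$multiome
    tf <- stats::setNames(mo$peaks$tf_bound, mo$peaks$id)
    prom <- stats::setNames(mo$genes$promoter_tf, mo$genes$gene_id)
    sc <- gene_linkage_score(links, tf, prom)
    linked_ids <- unique(links$peak_id[!is.na(links$class) &
                                         links$class == "positive"])
    bg_pool <- mo$peaks[!mo$peaks$id %in% linked_ids & !mo$peaks$tf_bound, ,
                        drop = FALSE]
    class(bg_pool) <- c("PeakSet", "data.frame")
    sc <- gene_target_enrichment(sc, links, tf, bg_pool,
                                 n_bg_sets = config$score$n_bg_sets %||% 25L,
                                 min_pairs = config$score$min_pairs %||% 3L,
                                 seed = config$seed)
    emit(write_gene_scores(sc, out("gene_target_scores.tsv")))
  }

  if (need("hic")) {
    log_msg("hic", "balancing, decay, compartments, insulation, APA")
    cm <- sim$contacts$matrix
    truth <- sim$contacts$truth
    bal <- balance_matrix(cm)
    dd <- distance_decay(bal)
    utils::write.table(
      data.frame(bin_mid_bp = dd$bin_mid, mean_count = dd$mean_count,
                 p_s = dd$p_s),
      out("distance_decay.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    emit(out("distance_decay.tsv"))
    comp <- compartments(bal)
    utils::write.table(
      data.frame(bin = seq_along(comp$e1), e1 = comp$e1,
                 label = comp$labels),
      out("compartments.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    emit(out("compartments.tsv"))
    ins <- insulation(bal, w = config$hic$insulation_w %||% 10L,
                      min_prominence = config$hic$min_prominence %||% 0.2)
    utils::write.table(
      data.frame(bin = seq_along(ins$score), score = ins$score,
                 boundary = seq_along(ins$score) %in% ins$boundaries),
      out("insulation.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    emit(out("insulation.tsv"))
    if (!is.null(truth$loop_anchors)) {
      ap <- apa(bal, truth$loop_anchors, W = config$hic$apa_W %||% 10L,
                expected = dd)
      utils::write.table(ap$map, out("apa_map.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      emit(out("apa_map.tsv"))
      jsonlite::write_json(list(center_enrichment = ap$center_enrichment,
                                n_pairs = ap$n_pairs),
                           out("apa_summary.json"), auto_unbox = TRUE,
                           digits = NA)
      emit(out("apa_summary.json"))
    }
  }

  if (need("methyl")) {
    log_msg("methyl", "CpG filtering and aggregation")
    track <- filter_cpgs(sim$methylome$track,
                         min_total = config$methyl$min_total %||% 10L)
    feats <- sim$methylome$truth$hypomethylated_features
    rm_ <- region_methylation(track, feats)
    utils::write.table(cbind(feats, mean_level = rm_),
                       out("region_methylation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(out("region_methylation.tsv"))
    prof <- meth_profile(track, feats,
                         flank_bp = config$methyl$flank_bp %||% 1000L,
                         n_bins = config$methyl$n_bins %||% 21L)
    utils::write.table(as.data.frame(prof), out("meth_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(out("meth_profile.tsv"))
  }

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("epiremod")),
    stages = config$stages,
    files = lapply(stats::setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(config$outdir, f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  log_msg("run", "wrote ", length(files), " output file(s) to ",
          config$outdir)
  invisible(manifest)
}
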