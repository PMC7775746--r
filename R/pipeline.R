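## End-to-end orchestration of the synthetic study: simulate, call
## confident peaks, classify and map to genes, Pol II metrics,
## super-enhancers, motif stratification and expression integration,
## with a machine-readable run manifest.

#' Pipeline run configuration
#'
#' Bundles the simulation configuration with every analysis threshold
#' (all of them the study's printed constants by default).
#'
#' @param sim `sim_config` for the synthetic study.
#' @param q_max confident-peak q-value bound.
#' @param min_reads,min_replicates confident-peak read and replicate
#'   bounds.
#' @param window_bp,step_bp,candidate_q peak-caller geometry and
#'   candidate threshold.
#' @param stitch_distance super-enhancer stitching distance (bp).
#' @param enhancer_window enhancer/SE target TSS window (bp).
#' @param promoter_upstream,promoter_downstream promoter target window
#'   (bp).
#' @param pol2_flank promoter-proximal half-width (bp).
#' @param motif_window summit window for motif stratification (bp).
#' @param density_half_window motif-density profile half-width (bp).
#' @param de_fold differential-expression fold threshold.
#' @param pseudocount RPM pseudocount for fold changes.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), q_max = 1e-7, min_reads = 5L,
                       min_replicates = 2L, window_bp = 300L,
                       step_bp = 50L, candidate_q = 0.01,
                       stitch_distance = 12500L,
                       enhancer_window = 50000L,
                       promoter_upstream = 1500L,
                       promoter_downstream = 250L,
                       pol2_flank = 250L, motif_window = 50L,
                       density_half_window = 200L, de_fold = 2,
                       pseudocount = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$q_max > 0, cfg$min_reads > 0, cfg$window_bp >= 50,
            cfg$stitch_distance > 0, cfg$enhancer_window > 0,
            cfg$promoter_upstream > 0, cfg$promoter_downstream > 0,
            cfg$pol2_flank > 0, cfg$motif_window > 0, cfg$de_fold > 1)
  if (cfg$min_replicates < 2)
    stop("min_replicates must be at least 2")
  validate_sim_config(cfg$sim)
  structure(cfg, class = "run_config")
}

#' Run the synthetic-study pipeline
#'
#' Stages run in dependency order: `simulate` (genome, coverage,
#' expression), `callpeaks` (confident peaks per factor and condition,
#' merged universe, combined signal, differential binding), `classify`
#' (chromatin classes, DNase-background enrichment), `targets`
#' (peak-to-gene assignment, Pr/Eh/Pr+Eh partition), `pol2` (densities,
#' pausing index, meta-gene profiles), `superenhancer`, `motifs`
#' (density profile and motif-stratified fold changes) and `integrate`
#' (expression records, bound-vs-unbound, DE and cancer enrichment).
#' Rerunning with the same configuration reproduces identical outputs.
#'
#' @param config `run_config`.
#' @param outdir output directory for TSV artifacts and the manifest;
#'   `NULL` for in-memory results only.
#' @param stages character vector of stage names or `"all"`.
#' @return invisible list of per-stage results (and `manifest` when
#'   `outdir` is given).
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL,
                         stages = "all") {
  all_stages <- c("simulate", "callpeaks", "classify", "targets", "pol2",
                  "superenhancer", "motifs", "integrate")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  ## dependencies are linear; run every stage up to the last requested
  stages <- all_stages[seq_len(max(match(stages, all_stages)))]
  res <- list(config = config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) message(sprintf("[%6.1fs] ",
                                       proc.time()[["elapsed"]] - t0), ...)

  say("simulate: seed ", config$sim$seed)
  sim <- simulate_study(config$sim)
  res$sim <- sim

  if ("callpeaks" %in% stages) {
    say("callpeaks")
    peaks <- list()
    for (fac in names(sim$chip)) {
      peaks[[fac]] <- list()
      for (cond in names(sim$chip[[fac]])) {
        p <- call_confident_peaks(
          sim$chip[[fac]][[cond]], sim$input[[cond]],
          q_max = config$q_max, min_replicates = config$min_replicates,
          min_reads = config$min_reads, window_bp = config$window_bp,
          step_bp = config$step_bp, candidate_q = config$candidate_q)
        p$signal <- p$count  # drives merged-summit selection
        peaks[[fac]][[cond]] <- p
      }
    }
    universe <- merge_peak_sets(list(
      peaks$S100A8$EtOH, peaks$S100A8$TAM,
      peaks$S100A9$EtOH, peaks$S100A9$TAM))
    ## summit-centric analyses use replicate- and factor-pooled coverage
    all_chip <- pool_tracks(c(sim$chip$S100A8$EtOH, sim$chip$S100A8$TAM,
                              sim$chip$S100A9$EtOH, sim$chip$S100A9$TAM))
    universe <- refine_summits(all_chip, universe)
    a8_rpm <- peak_signal_rpm(c(sim$chip$S100A8$EtOH,
                                sim$chip$S100A8$TAM), universe)
    a9_rpm <- peak_signal_rpm(c(sim$chip$S100A9$EtOH,
                                sim$chip$S100A9$TAM), universe)
    comb <- combined_signal(a8_rpm, a9_rpm)
    tam_tracks <- c(sim$chip$S100A8$TAM, sim$chip$S100A9$TAM)
    etoh_tracks <- c(sim$chip$S100A8$EtOH, sim$chip$S100A9$EtOH)
    diff <- differential_binding(universe, tam_tracks, etoh_tracks,
                                 pseudocount = config$pseudocount)
    res$peaks <- peaks; res$universe <- universe
    res$combined <- comb; res$diff <- diff
  }

  if ("classify" %in% stages) {
    say("classify: ", length(res$universe), " peaks")
    res$classes <- classify_peaks(res$universe, sim$states)
    dn <- sim$states$DNase
    res$dnase_classes <- classify_peaks(dn, sim$states)
    res$enrichment <- class_enrichment(res$classes, res$dnase_classes)
  }

  if ("targets" %in% stages) {
    say("targets")
    prom_peaks <- res$universe[res$classes == "promoter"]
    enh_peaks <- res$universe[res$classes == "enhancer"]
    res$promoter_targets <- assign_promoter_targets(
      prom_peaks, sim$genes, upstream = config$promoter_upstream,
      downstream = config$promoter_downstream)
    res$enhancer_targets <- assign_enhancer_targets(
      enh_peaks, sim$genes, max_dist = config$enhancer_window)
    res$target_classes <- gene_target_classes(res$promoter_targets,
                                              res$enhancer_targets)
  }

  if ("pol2" %in% stages) {
    say("pol2")
    res$pol2_metrics <- lapply(sim$pol2, pol2_gene_metrics,
                               genes = sim$genes,
                               flank = config$pol2_flank)
    tc <- setNames(res$target_classes$target_class,
                   res$target_classes$gene_id)
    grp <- tc[sim$genes$gene_id]
    grp[is.na(grp)] <- "unbound"
    res$metagene <- metagene_profile(sim$pol2$TAM, sim$genes, grp)
  }

  if ("superenhancer" %in% stages) {
    say("superenhancer")
    k27 <- sim$h3k27ac_peaks
    enh_only <- k27[!overlapsAny(k27, sim$states$H3K4me3)]
    chip_rpm <- rpm(region_counts(sim$h3k27ac$chip, enh_only),
                    track_depth(sim$h3k27ac$chip))
    in_rpm <- rpm(region_counts(sim$h3k27ac$input, enh_only),
                  track_depth(sim$h3k27ac$input))
    enh_only$signal <- chip_rpm
    enh_only$input_signal <- in_rpm
    st <- stitch_enhancers(enh_only, distance = config$stitch_distance)
    res$stitched <- call_super(st)
    res$se_peaks <- enh_only
    res$se_genes <- assign_se_genes(res$stitched, sim$genes,
                                    max_dist = config$enhancer_window)
  }

  if ("motifs" %in% stages) {
    say("motifs")
    res$motif_matrix <- peak_motif_matrix(sim$genome, res$universe,
                                          sim$pwms,
                                          window = config$motif_window)
    res$density_ap1 <- motif_density_profile(
      sim$genome, res$universe, sim$pwms$AP1,
      half_window = config$density_half_window)
    res$stratification <- stratify_fold_changes(res$diff$log2fc,
                                                res$motif_matrix)
  }

  if ("integrate" %in% stages) {
    say("integrate")
    res$records <- expression_records(sim$counts, sim$genes,
                                      sim$expr_depths,
                                      fold = config$de_fold)
    res$bound_vs_unbound <- bound_vs_unbound(
      res$records, res$target_classes$gene_id)
    catalog <- data.frame(
      gene_id = sim$truth$gene_id[sim$truth$catalog_label != "NonCancer"],
      label = sim$truth$catalog_label[sim$truth$catalog_label !=
                                        "NonCancer"])
    res$cancer_enrichment <- cancer_enrichment(
      catalog, res$target_classes$gene_id, sim$genes$gene_id)
  }

  if (!is.null(outdir)) {
    res$manifest <- write_pipeline_outputs(res, outdir)
  }
  say("done")
  invisible(res)
}

## write TSV artifacts plus a JSON manifest with config echo and hashes
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  if (!is.null(res$universe)) {
    u <- res$universe
    df <- data.frame(chrom = as.character(seqnames(u)),
                     start = start(u) - 1L, end = end(u),
                     summit = u$summit)
    if (!is.null(res$classes)) df$class <- as.character(res$classes)
    if (!is.null(res$diff)) {
      df$rpm_EtOH <- res$diff$rpm_etoh; df$rpm_TAM <- res$diff$rpm_tam
      df$log2fc <- res$diff$log2fc; df$q <- res$diff$q_value
    }
    wtsv(df, "peak_universe.tsv")
  }
  if (!is.null(res$enrichment)) wtsv(res$enrichment,
                                     "class_enrichment.tsv")
  if (!is.null(res$target_classes)) wtsv(res$target_classes,
                                         "gene_targets.tsv")
  if (!is.null(res$pol2_metrics))
    for (cond in names(res$pol2_metrics))
      wtsv(res$pol2_metrics[[cond]],
           sprintf("pol2_metrics_%s.tsv", cond))
  if (!is.null(res$stitched)) {
    s <- res$stitched
    wtsv(data.frame(chrom = as.character(seqnames(s)),
                    start = start(s) - 1L, end = end(s),
                    n_constituents = s$n_constituents,
                    signal = s$signal, rank = s$rank,
                    is_super = s$is_super),
         "superenhancers.tsv")
  }
  if (!is.null(res$stratification)) wtsv(res$stratification,
                                         "motif_stratification.tsv")
  if (!is.null(res$records)) wtsv(res$records, "expression_records.tsv")
  if (!is.null(res$cancer_enrichment)) wtsv(res$cancer_enrichment,
                                            "cancer_enrichment.tsv")
  cfg <- res$config
  cfg$sim <- unclass(cfg$sim)
  manifest <- list(
    package = "chipcoact",
    version = as.character(utils::packageVersion("chipcoact")),
    seed = res$config$sim$seed,
    config = unclass(cfg),
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)),
           rows = length(readLines(p)) - 1L)))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}
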