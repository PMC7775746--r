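## Seeded synthetic-study generator: a miniature two-condition (EtOH vs
## TAM) ChIP study for two factors (S100A8, S100A9) with planted ground
## truth for every downstream stage -- site classes and fold changes,
## motif-bearing summits, Pol II pausing, binding-coupled expression and
## cancer-gene labels.

#' Default synthetic transcription-factor motifs
#'
#' A small synthetic motif panel named after the motif families recurrently
#' found at coactivator-bound regulatory regions (AP-1, CREB, ETS, KLF/SP1,
#' CEBP). Matrices are built from consensus strings with 85/5/5/5 column
#' counts; they are synthetic stand-ins, not JASPAR entries.
#'
#' @param score_frac hit threshold as fraction of maximum score.
#' @return named list of `pwm` objects.
#' @export
default_pwms <- function(score_frac = 0.8) {
  cons <- c(AP1 = "TGACTCA", CREB = "TGACGTCA", ETS = "ACAGGAAGT",
            KLF = "GGGGCGGGG", CEBP = "TTGCGCAAT")
  base_row <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  out <- lapply(names(cons), function(nm) {
    b <- strsplit(cons[[nm]], "")[[1]]
    m <- matrix(5, nrow = 4, ncol = length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    m[cbind(base_row[b], seq_along(b))] <- 85
    new_pwm(nm, m, pseudocount = 1, score_frac = score_frac)
  })
  names(out) <- names(cons)
  out
}

pwm_consensus <- function(pwm) {
  paste(rownames(pwm$prob)[apply(pwm$prob, 2, which.max)], collapse = "")
}

#' Configuration of the synthetic study
#'
#' Defaults describe the emulated design: 2 conditions x 2 factors x 2
#' replicates of ChIP coverage over a 3 x 2 Mb genome with 300 genes and
#' 400 planted binding sites whose chromatin-class composition
#' (promoter/enhancer/repressed/uncharacterized = 120/180/24/76) mirrors
#' the 30/45/6/19 percent split observed for S100A8/A9 sites. Binding is
#' induced on transformation (median 2-fold, log-normal spread), AP-1
#' motif-bearing sites receive an extra induction boost, pausing indices
#' are log-normal around 4, and expression fold changes are coupled to
#' binding.
#'
#' @param seed integer RNG seed; the whole study is a deterministic
#'   function of it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes number of non-overlapping genes.
#' @param n_sites named integer vector of planted site counts per class
#'   (`promoter`, `enhancer`, `repressed`, `null`).
#' @param replicates ChIP replicates per factor and condition (>= 2).
#' @param site_width planted site width in bp.
#' @param input_depth expected input reads per sample; also sets the
#'   ChIP background rate.
#' @param chip_enrichment median site amplitude (fold over background).
#' @param amp_sdlog log-sd of site amplitudes.
#' @param factor_cor target correlation of S100A8 vs S100A9 log
#'   amplitudes.
#' @param binding_lfc_mean,binding_lfc_sd normal parameters of the planted
#'   TAM:EtOH log2 binding fold change.
#' @param ap1_boost extra log2 fold change at AP-1 motif-bearing sites.
#' @param motif_probs per-summit placement probability per motif.
#' @param pausing_meanlog,pausing_sdlog log-normal parameters of the
#'   planted pausing index.
#' @param pol2_depth,expr_depth Pol II track and footprint library depths.
#' @param expr_base_mean,expr_base_sd log2 RPKM baseline distribution.
#' @param bound_expr_boost log2 expression offset of bound genes.
#' @param preh_expr_boost additional log2 offset for genes with both
#'   promoter and enhancer sites (combined regulatory input drives the
#'   strongest transcription).
#' @param expr_coupling log2 expression fold change per unit planted
#'   binding log2 fold change.
#' @param expr_noise_sd residual sd of expression log2 fold changes.
#' @param cancer_frac_bound,cancer_frac_unbound cancer-gene probability
#'   for bound and unbound genes.
#' @param cancer_split proportions of cancer genes labelled ONG, TSG,
#'   OncoTSG.
#' @param n_background_enhancers enhancer-state regions without planted
#'   factor binding.
#' @param n_superenhancers,se_constituents,se_amp_fold planted
#'   super-enhancer clusters: count, constituents each, H3K27ac
#'   amplitude multiplier.
#' @param n_dnase,dnase_mix DNase background site count and class mix.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L, chrom_length = 2e6,
                       n_genes = 300L,
                       n_sites = c(promoter = 120L, enhancer = 180L,
                                   repressed = 24L, null = 76L),
                       replicates = 2L,
                       site_width = 300L,
                       input_depth = 1e6,
                       chip_enrichment = 12,
                       amp_sdlog = 0.5,
                       factor_cor = 0.9,
                       binding_lfc_mean = 1, binding_lfc_sd = 0.6,
                       ap1_boost = 0.5,
                       motif_probs = c(AP1 = 0.4, CREB = 0.25, ETS = 0.3,
                                       KLF = 0.25, CEBP = 0.2),
                       pausing_meanlog = log(4), pausing_sdlog = 0.6,
                       pol2_depth = 2e6, expr_depth = 2e6,
                       expr_base_mean = 3, expr_base_sd = 1.5,
                       bound_expr_boost = 1, preh_expr_boost = 1,
                       expr_coupling = 0.5, expr_noise_sd = 0.3,
                       cancer_frac_bound = 0.10,
                       cancer_frac_unbound = 0.04,
                       cancer_split = c(ONG = 0.35, TSG = 0.54,
                                        OncoTSG = 0.11),
                       n_background_enhancers = 150L,
                       n_superenhancers = 10L, se_constituents = 3L,
                       se_amp_fold = 8,
                       n_dnase = 1500L,
                       dnase_mix = c(promoter = 0.15, enhancer = 0.25,
                                     repressed = 0.20, null = 0.40)) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$replicates >= 2,
            cfg$n_chroms >= 1, cfg$chrom_length >= 1e5,
            all(cfg$n_sites >= 0),
            all(names(cfg$n_sites) ==
                  c("promoter", "enhancer", "repressed", "null")),
            all(cfg$motif_probs >= 0 & cfg$motif_probs <= 1),
            cfg$cancer_frac_bound >= 0, cfg$cancer_frac_bound <= 1,
            cfg$cancer_frac_unbound >= 0, cfg$cancer_frac_unbound <= 1,
            abs(sum(cfg$cancer_split) - 1) < 1e-6,
            abs(sum(cfg$dnase_mix) - 1) < 1e-6,
            cfg$site_width >= 50, cfg$input_depth > 0)
  invisible(cfg)
}

## evenly distribute n items over k bins
.split_n <- function(n, k) {
  base <- n %/% k
  out <- rep(base, k)
  if (n %% k > 0) out[seq_len(n %% k)] <- out[seq_len(n %% k)] + 1L
  out
}

#' Simulate the genome, genes, chromatin states and ground-truth sites
#'
#' Lays out non-overlapping genes on each chromosome (the last 15 percent
#' of every chromosome is reserved for repressed blocks and planted
#' super-enhancer clusters), places the planted binding sites per class,
#' the histone-mark segmentation, DNase background sites, and a uniform
#' random sequence with motif consensus strings planted at site summits.
#'
#' @param config `sim_config`.
#' @return list of class `genome_sim` with elements `config`,
#'   `chrom_lengths`, `genome` (`DNAStringSet`), `genes` (`GRanges`),
#'   `states` (per-mark `GRanges` list including `DNase`), `sites`
#'   (`GRanges` with planted class, fold change, amplitudes, motifs),
#'   `h3k27ac_peaks`, `pwms`, and per-gene ground truth `truth`.
#' @export
simulate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  cl <- setNames(rep(as.integer(config$chrom_length), config$n_chroms),
                 paste0("chr", seq_len(config$n_chroms)))
  genic_end <- floor(0.85 * config$chrom_length)

  ## ---- genes ----
  per_chrom <- .split_n(config$n_genes, config$n_chroms)
  gene_rows <- list()
  gap_rows <- list()    # intergenic gaps inside the genic zone
  for (ci in seq_len(config$n_chroms)) {
    n <- per_chrom[ci]
    if (n == 0) next
    lens <- sample(3000:12000, n, replace = TRUE)
    gaps <- 2000 + round(rexp(n, rate = 1 / 3000))
    starts <- integer(n); pos <- 2000L
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + lens[i]
    }
    if (pos > genic_end)
      stop(sprintf("genome too small: need %d bp of genic zone on %s, have %d",
                   pos, names(cl)[ci], genic_end))
    gene_rows[[ci]] <- data.frame(
      chrom = names(cl)[ci], start = starts, end = starts + lens - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE))
    gap_rows[[ci]] <- data.frame(
      chrom = names(cl)[ci],
      start = starts - gaps[seq_len(n)], end = starts - 1L)
    gap_rows[[ci]] <- rbind(gap_rows[[ci]],
      data.frame(chrom = names(cl)[ci],
                 start = starts[n] + lens[n], end = genic_end))
  }
  gdf <- do.call(rbind, gene_rows)
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand)
  genes$gene_id <- sprintf("g%04d", seq_along(genes))
  plus <- gdf$strand == "+"
  genes$tss <- ifelse(plus, gdf$start, gdf$end)
  genes$tes <- ifelse(plus, gdf$end, gdf$start)
  cds_off5 <- 150L + sample(0:150, length(genes), replace = TRUE)
  cds_off3 <- 100L + sample(0:150, length(genes), replace = TRUE)
  genes$has_orf <- TRUE
  genes$cds_start <- gdf$start + cds_off5
  genes$cds_end <- gdf$end - cds_off3
  genes$gene_length <- width(genes)

  ## ---- promoter sites ----
  ns <- config$n_sites
  if (ns[["promoter"]] > length(genes))
    stop("genome too small: more promoter sites requested than genes")
  prom_gene_idx <- sample(length(genes), ns[["promoter"]])
  off <- sample(-200:100, ns[["promoter"]], replace = TRUE)  # strand-aware
  prom_tss <- genes$tss[prom_gene_idx]
  prom_strand <- as.character(strand(genes))[prom_gene_idx]
  prom_summit <- ifelse(prom_strand == "+", prom_tss + off, prom_tss - off)
  prom_chrom <- as.character(seqnames(genes))[prom_gene_idx]

  ## ---- H3K4me3 promoter mark ----
  k4me3_genes <- union(prom_gene_idx,
                       sample(setdiff(seq_along(genes), prom_gene_idx),
                              floor(0.5 * (length(genes) -
                                             ns[["promoter"]])) ))
  k4me3 <- GRanges(seqnames(genes)[k4me3_genes],
                   IRanges(pmax(1, genes$tss[k4me3_genes] - 700),
                           genes$tss[k4me3_genes] + 700))

  ## ---- intergenic slots for enhancer / null placement ----
  gapdf <- do.call(rbind, gap_rows)
  gapdf <- gapdf[gapdf$end - gapdf$start > 4200, , drop = FALSE]
  slots <- list()
  for (i in seq_len(nrow(gapdf))) {
    lo <- gapdf$start[i] + 1500; hi <- gapdf$end[i] - 1500
    k <- floor((hi - lo) / 1500)
    if (k < 1) next
    slots[[i]] <- data.frame(chrom = gapdf$chrom[i],
                             pos = lo + 750 + 1500 * (seq_len(k) - 1L))
  }
  slots <- do.call(rbind, slots)
  slots <- slots[sample(nrow(slots)), , drop = FALSE]
  n_enh_needed <- ns[["enhancer"]] + config$n_background_enhancers
  n_null <- ns[["null"]]
  if (nrow(slots) < n_enh_needed + n_null)
    stop(sprintf("genome too small: %d intergenic slots available, %d needed",
                 nrow(slots), n_enh_needed + n_null))
  enh_slots <- slots[seq_len(n_enh_needed), ]
  null_slots <- slots[n_enh_needed + seq_len(n_null), ]
  enh_summit <- enh_slots$pos[seq_len(ns[["enhancer"]])]
  enh_chrom <- enh_slots$chrom[seq_len(ns[["enhancer"]])]
  bg_enh <- enh_slots[ns[["enhancer"]] + seq_len(config$n_background_enhancers), ]

  ## ---- tail zone: super-enhancer clusters and repressed blocks ----
  tail_start <- genic_end + 10000
  se_per_chrom <- .split_n(config$n_superenhancers, config$n_chroms)
  se_rows <- list()
  for (ci in seq_len(config$n_chroms)) {
    if (se_per_chrom[ci] == 0) next
    orig <- tail_start + 30000 * (seq_len(se_per_chrom[ci]) - 1L)
    for (k in seq_len(se_per_chrom[ci])) {
      cpos <- orig[k] + 4000 * (seq_len(config$se_constituents) - 1L)
      se_rows[[length(se_rows) + 1L]] <- data.frame(
        chrom = names(cl)[ci], center = cpos + 500,
        cluster = sprintf("SE_%s_%d", names(cl)[ci], k))
    }
  }
  sedf <- do.call(rbind, se_rows)
  if (max(sedf$center) + 2000 > config$chrom_length)
    stop("genome too small for requested super-enhancer clusters")

  rep_zone_start <- tail_start + 30000 * max(se_per_chrom) + 10000
  rep_blocks <- GRanges(rep(names(cl), each = 3),
                        IRanges(rep(rep_zone_start + c(0, 12000, 24000),
                                    config$n_chroms),
                                width = 8000))
  if (max(end(rep_blocks)) > config$chrom_length)
    stop("genome too small for repressed blocks")
  rep_per_block <- .split_n(ns[["repressed"]], length(rep_blocks))
  rep_chrom <- character(0); rep_summit <- integer(0)
  for (b in seq_along(rep_blocks)) {
    if (rep_per_block[b] == 0) next
    p <- start(rep_blocks)[b] + 1500 + 1500 * (seq_len(rep_per_block[b]) - 1L)
    rep_chrom <- c(rep_chrom, rep(as.character(seqnames(rep_blocks))[b],
                                  rep_per_block[b]))
    rep_summit <- c(rep_summit, p)
  }

  ## ---- assemble planted sites ----
  site_chrom <- c(prom_chrom, enh_chrom, rep_chrom, null_slots$chrom)
  site_summit <- as.integer(c(prom_summit, enh_summit, rep_summit,
                              null_slots$pos))
  site_class <- rep(c("promoter", "enhancer", "repressed", "null"),
                    times = c(ns[["promoter"]], ns[["enhancer"]],
                              ns[["repressed"]], ns[["null"]]))
  hw <- floor(config$site_width / 2)
  sites <- GRanges(site_chrom,
                   IRanges(pmax(1, site_summit - hw), site_summit + hw))
  sites$summit <- site_summit
  sites$class <- site_class
  sites$site_id <- sprintf("site%04d", seq_along(sites))
  sites$target_gene <- rep(NA_character_, length(sites))
  sites$target_gene[seq_len(ns[["promoter"]])] <-
    genes$gene_id[prom_gene_idx]

  ## ---- motifs planted at summits ----
  pwms <- default_pwms()
  mp <- config$motif_probs
  mp <- mp[names(mp) %in% names(pwms)]
  motif_mat <- matrix(FALSE, length(sites), length(mp),
                      dimnames = list(NULL, names(mp)))
  for (m in names(mp))
    motif_mat[, m] <- runif(length(sites)) < mp[[m]]
  sites$motifs <- if (length(sites)) apply(motif_mat, 1, function(z)
    paste(colnames(motif_mat)[z], collapse = ",")) else character(0)

  ## ---- planted amplitudes and fold changes ----
  n_site <- length(sites)
  rho <- config$factor_cor
  z0 <- rnorm(n_site); z1 <- rnorm(n_site); z2 <- rnorm(n_site)
  s <- config$amp_sdlog
  mu <- log(config$chip_enrichment)
  sites$amp_a8 <- exp(mu + s * (sqrt(rho) * z0 + sqrt(1 - rho) * z1))
  sites$amp_a9 <- exp(mu + s * (sqrt(rho) * z0 + sqrt(1 - rho) * z2))
  sites$log2fc <- rnorm(n_site, config$binding_lfc_mean,
                        config$binding_lfc_sd) +
    config$ap1_boost * motif_mat[, "AP1"]

  ## ---- chromatin-state maps ----
  ## H3K4me1 marks every enhancer region (planted sites and background);
  ## H3K27ac -- the super-enhancer substrate -- only marks background
  ## enhancers spaced beyond the stitching distance, plus the planted
  ## super-enhancer clusters, so stitched background regions stay simple.
  k4me1_pos <- c(enh_summit, bg_enh$pos)
  k4me1_chr <- c(enh_chrom, bg_enh$chrom)
  k4me1 <- GRanges(k4me1_chr, IRanges(k4me1_pos - 500, k4me1_pos + 499))
  spaced <- logical(nrow(bg_enh))
  for (ch in unique(bg_enh$chrom)) {
    i <- which(bg_enh$chrom == ch)
    i <- i[order(bg_enh$pos[i])]
    last <- -Inf
    for (j in i) {
      if (bg_enh$pos[j] - last >= 14000) { spaced[j] <- TRUE
        last <- bg_enh$pos[j] }
    }
  }
  bg_k27 <- bg_enh[spaced, , drop = FALSE]
  enh_all_pos <- c(bg_k27$pos, sedf$center)
  enh_all_chr <- c(bg_k27$chrom, sedf$chrom)
  k27ac <- GRanges(enh_all_chr, IRanges(enh_all_pos - 500, enh_all_pos + 499))
  k27ac$amp <- exp(rnorm(length(k27ac), log(6), 0.4))
  nse <- nrow(sedf)
  k27ac$se_cluster <- NA_character_
  se_idx <- length(enh_all_pos) - nse + seq_len(nse)
  k27ac$se_cluster[se_idx] <- sedf$cluster
  k27ac$amp[se_idx] <- k27ac$amp[se_idx] * config$se_amp_fold
  k9me3 <- rep_blocks
  k27me3 <- rep_blocks[sample(length(rep_blocks),
                              ceiling(0.6 * length(rep_blocks)))]

  ## ---- DNase background sites ----
  nd <- round(config$n_dnase * config$dnase_mix)
  dn_chrom <- character(0); dn_pos <- integer(0)
  g_k4 <- k4me3_genes
  i <- sample(g_k4, nd[["promoter"]], replace = TRUE)
  dn_chrom <- c(dn_chrom, as.character(seqnames(genes))[i])
  dn_pos <- c(dn_pos, genes$tss[i] + sample(-300:300, nd[["promoter"]],
                                            replace = TRUE))
  enh_regions <- c(GRanges(seqnames(k4me1), IRanges(start(k4me1),
                                                    end(k4me1))),
                   GRanges(seqnames(k27ac), IRanges(start(k27ac),
                                                    end(k27ac))))
  i <- sample(length(enh_regions), nd[["enhancer"]], replace = TRUE)
  dn_chrom <- c(dn_chrom, as.character(seqnames(enh_regions))[i])
  dn_pos <- c(dn_pos, floor((start(enh_regions)[i] +
                               end(enh_regions)[i]) / 2) +
                sample(-300:300, nd[["enhancer"]], replace = TRUE))
  i <- sample(length(rep_blocks), nd[["repressed"]], replace = TRUE)
  dn_chrom <- c(dn_chrom, as.character(seqnames(rep_blocks))[i])
  dn_pos <- c(dn_pos, start(rep_blocks)[i] +
                sample(500:9500, nd[["repressed"]], replace = TRUE))
  extra <- slots[-seq_len(min(nrow(slots), n_enh_needed + n_null)), ,
                 drop = FALSE]
  if (nrow(extra) >= nd[["null"]]) {
    i <- sample(nrow(extra), nd[["null"]])
    dn_chrom <- c(dn_chrom, extra$chrom[i])
    dn_pos <- c(dn_pos, extra$pos[i])
  } else {  # fall back to unmarked tail positions
    i <- sample(config$n_chroms, nd[["null"]], replace = TRUE)
    dn_chrom <- c(dn_chrom, names(cl)[i])
    dn_pos <- c(dn_pos, sample(seq(genic_end + 1000, tail_start - 1000),
                               nd[["null"]], replace = TRUE))
  }
  dn_pos <- pmax(100L, as.integer(dn_pos))
  dnase <- GRanges(dn_chrom, IRanges(dn_pos - 75, dn_pos + 75))
  dnase$summit <- dn_pos

  ## ---- sequence with planted consensus strings ----
  genome <- DNAStringSet(vapply(cl, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  names(genome) <- names(cl)
  plant_offsets <- c(0L, 15L, -15L, 30L, -30L)
  for (si in seq_len(n_site)) {
    planted <- colnames(motif_mat)[motif_mat[si, ]]
    if (length(planted) == 0) next
    ch <- site_chrom[si]
    for (k in seq_along(planted)) {
      cons <- pwm_consensus(pwms[[planted[k]]])
      L <- nchar(cons)
      center <- site_summit[si] + plant_offsets[k]
      s0 <- center - floor(L / 2)
      if (s0 < 1 || s0 + L - 1 > cl[[ch]]) next
      subseq(genome[[ch]], s0, s0 + L - 1) <- DNAString(cons)
    }
  }

  ## ---- gene-level ground truth ----
  prom_targets <- unique(genes$gene_id[prom_gene_idx])
  enh_sites <- sites[sites$class == "enhancer"]
  tssgr <- GRanges(seqnames(genes), IRanges(genes$tss, width = 1L))
  win <- GRanges(seqnames(enh_sites),
                 IRanges(pmax(1, enh_sites$summit - 50000),
                         enh_sites$summit + 50000))
  ov <- findOverlaps(tssgr, win)
  enh_targets <- unique(genes$gene_id[queryHits(ov)])
  tclass <- rep("unbound", length(genes))
  tclass[genes$gene_id %in% prom_targets] <- "Pr"
  tclass[genes$gene_id %in% enh_targets] <- "Eh"
  tclass[genes$gene_id %in% intersect(prom_targets, enh_targets)] <- "Pr+Eh"
  bound <- tclass != "unbound"

  ## mean planted site fold change per gene (promoter sites mapped to the
  ## chosen gene; enhancer sites to every gene within the 50 kb window)
  lfc_sum <- setNames(numeric(length(genes)), genes$gene_id)
  lfc_n <- setNames(numeric(length(genes)), genes$gene_id)
  pg <- sites$target_gene[sites$class == "promoter"]
  plfc <- sites$log2fc[sites$class == "promoter"]
  for (i in seq_along(pg)) {
    lfc_sum[pg[i]] <- lfc_sum[pg[i]] + plfc[i]
    lfc_n[pg[i]] <- lfc_n[pg[i]] + 1
  }
  elfc <- enh_sites$log2fc
  for (i in seq_len(length(ov))) {
    gid <- genes$gene_id[queryHits(ov)[i]]
    lfc_sum[gid] <- lfc_sum[gid] + elfc[subjectHits(ov)[i]]
    lfc_n[gid] <- lfc_n[gid] + 1
  }
  gene_lfc <- ifelse(lfc_n > 0, lfc_sum / pmax(lfc_n, 1), 0)

  pausing <- rlnorm(length(genes), config$pausing_meanlog,
                    config$pausing_sdlog)
  expr_base <- rnorm(length(genes), config$expr_base_mean,
                     config$expr_base_sd) +
    config$bound_expr_boost * bound +
    config$preh_expr_boost * (tclass == "Pr+Eh")
  expr_lfc <- config$expr_coupling * gene_lfc +
    rnorm(length(genes), 0, config$expr_noise_sd)

  p_cancer <- ifelse(bound, config$cancer_frac_bound,
                     config$cancer_frac_unbound)
  is_cancer <- runif(length(genes)) < p_cancer
  label <- rep("NonCancer", length(genes))
  label[is_cancer] <- sample(names(config$cancer_split), sum(is_cancer),
                             replace = TRUE, prob = config$cancer_split)

  truth <- data.frame(gene_id = genes$gene_id,
                      target_class = tclass, bound = bound,
                      binding_lfc = as.numeric(gene_lfc),
                      pausing_index = pausing,
                      expr_base_log2 = expr_base,
                      expr_lfc = expr_lfc,
                      catalog_label = label,
                      stringsAsFactors = FALSE)

  structure(list(config = config, chrom_lengths = cl, genome = genome,
                 genes = genes,
                 states = list(H3K4me3 = k4me3, H3K4me1 = k4me1,
                               H3K27ac = GRanges(seqnames(k27ac),
                                                 IRanges(start(k27ac),
                                                         end(k27ac))),
                               H3K9me3 = k9me3, H3K27me3 = k27me3,
                               DNase = dnase),
                 sites = sites, h3k27ac_peaks = k27ac, pwms = pwms,
                 truth = truth),
            class = "genome_sim")
}

## lambda profile for one sample: flat background plus triangular site
## kernels (expected extra reads per site = amp * base * site_width)
.lambda_tracks <- function(chrom_lengths, base, centers, chroms, extra,
                           half_width) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    lam <- rep(base, chrom_lengths[[ch]])
    idx <- which(chroms == ch)
    for (i in idx) {
      c0 <- centers[i]
      lo <- max(1L, c0 - half_width); hi <- min(chrom_lengths[[ch]],
                                                c0 + half_width)
      x <- lo:hi
      lam[x] <- lam[x] + 2 * extra[i] * base * (1 - abs(x - c0) / half_width)
    }
    out[[ch]] <- lam
  }
  out
}

.sample_track <- function(lambda_tracks) {
  lapply(lambda_tracks, function(lam) Rle(rpois(length(lam), lam)))
}

#' Simulate ChIP and input coverage for both factors and conditions
#'
#' Read-start counts are Poisson: flat background everywhere, plus a
#' triangular kernel at every planted site whose expected extra reads are
#' `amplitude x background x site_width`, multiplied in the TAM condition
#' by the planted fold change `2^log2fc`. S100A8 and S100A9 share sites
#' with correlated amplitudes. Also generates the H3K27ac track (with
#' planted super-enhancer clusters) and matched flat inputs.
#'
#' @param sim `genome_sim` from [simulate_genome()].
#' @return list with `chip[[factor]][[condition]][[replicate]]` coverage
#'   tracks, `input[[condition]]`, `h3k27ac` (`chip`/`input`), and
#'   `depths` mirroring the structure.
#' @export
simulate_chip <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 1L)
  cl <- sim$chrom_lengths
  base <- cfg$input_depth / sum(cl)
  hw <- floor(cfg$site_width / 2)
  ch <- as.character(seqnames(sim$sites))
  centers <- sim$sites$summit
  fold_tam <- 2^sim$sites$log2fc

  chip <- list()
  for (fac in c("S100A8", "S100A9")) {
    amp <- if (fac == "S100A8") sim$sites$amp_a8 else sim$sites$amp_a9
    chip[[fac]] <- list()
    for (cond in c("EtOH", "TAM")) {
      mult <- if (cond == "TAM") fold_tam else rep(1, length(centers))
      lam <- .lambda_tracks(cl, base, centers, ch, amp * mult, hw)
      chip[[fac]][[cond]] <- lapply(seq_len(cfg$replicates),
                                    function(r) .sample_track(lam))
      names(chip[[fac]][[cond]]) <- paste0("rep", seq_len(cfg$replicates))
    }
  }
  input <- list(
    EtOH = .sample_track(lapply(cl, function(L) rep(base, L))),
    TAM = .sample_track(lapply(cl, function(L) rep(base, L))))

  k27 <- sim$h3k27ac_peaks
  k27_centers <- floor((start(k27) + end(k27)) / 2)
  lam27 <- .lambda_tracks(cl, base, k27_centers,
                          as.character(seqnames(k27)), k27$amp,
                          floor(width(k27)[1] / 2))
  h3k27ac <- list(chip = .sample_track(lam27),
                  input = .sample_track(lapply(cl, function(L)
                    rep(base, L))))
  list(chip = chip, input = input, h3k27ac = h3k27ac)
}

#' Simulate Pol II coverage and ribosome-footprint counts
#'
#' Pol II: per gene, the gene-body rate is proportional to the
#' condition-specific expression level and the promoter-proximal window
#' (TSS +/- 250 bp) rate is the body rate times the planted pausing index;
#' the genome-wide profile is rescaled to the configured depth and
#' Poisson-sampled. Footprints: per-gene Poisson counts over the trimmed
#' ORF targeting `RPKM = 2^(expression log2)` at the configured depth.
#'
#' @param sim `genome_sim`.
#' @return list with `pol2[[condition]]` coverage tracks, `pol2_depths`,
#'   `counts` (data.frame `gene_id`, `reads_EtOH`, `reads_TAM`,
#'   `region_bp`), and `expr_depths`.
#' @export
simulate_pol2_and_expression <- function(sim) {
  cfg <- sim$config
  set.seed(cfg$seed + 2L)
  cl <- sim$chrom_lengths
  genes <- sim$genes
  truth <- sim$truth
  lvl <- list(EtOH = truth$expr_base_log2,
              TAM = truth$expr_base_log2 + truth$expr_lfc)

  pol2 <- list(); pol2_depths <- c(EtOH = 0, TAM = 0)
  for (cond in c("EtOH", "TAM")) {
    lam <- lapply(cl, function(L) rep(0.005, L))
    for (i in seq_along(genes)) {
      chn <- as.character(seqnames(genes))[i]
      body_rate <- 2^lvl[[cond]][i] / 200   # relative units, rescaled below
      s <- start(genes)[i]; e <- end(genes)[i]
      lam[[chn]][s:e] <- lam[[chn]][s:e] + body_rate
      ## promoter-proximal rate = body rate x pausing index over the whole
      ## +/-250 bp window (genes are spaced, so overwriting is exact)
      tss <- genes$tss[i]
      pw <- max(1L, tss - 250L):min(cl[[chn]], tss + 250L)
      lam[[chn]][pw] <- 0.005 + body_rate * truth$pausing_index[i]
    }
    tot <- sum(vapply(lam, sum, numeric(1)))
    lam <- lapply(lam, function(v) v * cfg$pol2_depth / tot)
    pol2[[cond]] <- .sample_track(lam)
    pol2_depths[cond] <- track_depth(pol2[[cond]])
  }

  region_bp <- trimmed_orf_length(genes)
  counts <- data.frame(gene_id = genes$gene_id, region_bp = region_bp)
  for (cond in c("EtOH", "TAM")) {
    mu <- 2^lvl[[cond]] * (region_bp / 1000) * (cfg$expr_depth / 1e6)
    mu[is.na(mu)] <- 0
    counts[[paste0("reads_", cond)]] <- rpois(length(mu), mu)
  }
  list(pol2 = pol2, pol2_depths = pol2_depths, counts = counts,
       expr_depths = c(EtOH = cfg$expr_depth, TAM = cfg$expr_depth))
}

#' Simulate a complete synthetic study
#'
#' @param config `sim_config`.
#' @return list of class `study_sim` combining [simulate_genome()],
#'   [simulate_chip()] and [simulate_pol2_and_expression()] outputs.
#' @export
simulate_study <- function(config = sim_config()) {
  g <- simulate_genome(config)
  chipsim <- simulate_chip(g)
  pe <- simulate_pol2_and_expression(g)
  structure(c(g, chipsim, pe), class = "study_sim")
}

#' Write the text-format inputs of a simulated study to a directory
#'
#' Writes the genome FASTA, gene table, per-mark state BEDs, planted-site
#' ground truth TSV, footprint count table and, optionally, coverage
#' bedGraphs (off by default: they are large and regenerable from the
#' seed).
#'
#' @param sim `study_sim` or `genome_sim`.
#' @param dir output directory (created).
#' @param coverage also write all coverage tracks as bedGraph.
#' @return invisibly, the vector of files written.
#' @export
write_study <- function(sim, dir, coverage = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wf <- function(p) { files <<- c(files, p); p }
  writeXStringSet(sim$genome, wf(file.path(dir, "genome.fa")))
  write_gene_table(sim$genes, wf(file.path(dir, "genes.tsv")))
  for (mark in names(sim$states))
    write_bed(sim$states[[mark]],
              wf(file.path(dir, paste0("state_", mark, ".bed"))))
  st <- sim$sites
  df <- data.frame(chrom = as.character(seqnames(st)),
                   start = start(st) - 1L, end = end(st),
                   summit = st$summit, class = st$class,
                   site_id = st$site_id, log2fc = st$log2fc,
                   amp_a8 = st$amp_a8, amp_a9 = st$amp_a9,
                   motifs = st$motifs)
  write.table(df, wf(file.path(dir, "truth_sites.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth, wf(file.path(dir, "truth_genes.tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_jaspar(sim$pwms, wf(file.path(dir, "motifs.jaspar.txt")))
  if (!is.null(sim$counts))
    write.table(sim$counts, wf(file.path(dir, "footprint_counts.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (coverage && !is.null(sim$chip)) {
    for (fac in names(sim$chip))
      for (cond in names(sim$chip[[fac]]))
        for (r in names(sim$chip[[fac]][[cond]]))
          write_coverage(sim$chip[[fac]][[cond]][[r]],
                         wf(file.path(dir, sprintf("chip_%s_%s_%s.bedgraph",
                                                   fac, cond, r))))
    for (cond in names(sim$input))
      write_coverage(sim$input[[cond]],
                     wf(file.path(dir, sprintf("input_%s.bedgraph", cond))))
  }
  invisible(files)
}
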