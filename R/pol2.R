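## Pol II density, pausing index and meta-gene profiles.

#' Pol II density and pausing index per gene
#'
#' The promoter-proximal window is TSS +/- `flank` bp (symmetric, so
#' strand orientation does not change it); the gene body is the gene
#' interval minus its intersection with that window. Densities are
#' RPM/kb. The pausing index (traveling ratio) is promoter density over
#' body density; it is reported as `NA` when the body density is zero,
#' never 0 or infinity. Genes not longer than `min_length` bp, or whose
#' promoter window extends beyond the chromosome, are excluded with a
#' reason code.
#'
#' @param track Pol II coverage track.
#' @param genes gene `GRanges` with `tss` metadata.
#' @param flank promoter-proximal half-width in bp.
#' @param min_length minimum gene length in bp (exclusive bound).
#' @return data.frame `gene_id`, `promoter_reads`, `body_reads`,
#'   `promoter_density`, `body_density`, `pausing_index`, `status`
#'   (`ok`, `short_gene`, `edge_gene`, `no_body_signal`).
#' @export
pol2_gene_metrics <- function(track, genes, flank = 250L,
                              min_length = 251L) {
  depth <- track_depth(track)
  stopifnot(depth > 0)
  n <- length(genes)
  chrom <- as.character(seqnames(genes))
  chrom_len <- vapply(track, length, integer(1))
  out <- data.frame(gene_id = genes$gene_id,
                    promoter_reads = NA_real_, body_reads = NA_real_,
                    promoter_density = NA_real_, body_density = NA_real_,
                    pausing_index = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  short <- genes$gene_length <= min_length
  ps <- genes$tss - flank
  pe <- genes$tss + flank
  edge <- ps < 1 | pe > chrom_len[chrom]
  out$status[short] <- "short_gene"
  out$status[!short & edge] <- "edge_gene"
  use <- which(!short & !edge)
  if (length(use) == 0L) return(out)
  prom <- GRanges(chrom[use], IRanges(ps[use], pe[use]))
  prom_reads <- region_counts(track, prom)
  gene_reads <- region_counts(track, GRanges(chrom[use],
                                             IRanges(start(genes)[use],
                                                     end(genes)[use])))
  ## body = gene minus the promoter-window overlap
  ov_s <- pmax(start(genes)[use], ps[use])
  ov_e <- pmin(end(genes)[use], pe[use])
  ov_w <- pmax(0, ov_e - ov_s + 1)
  ov_reads <- numeric(length(use))
  hasov <- ov_w > 0
  if (any(hasov))
    ov_reads[hasov] <- region_counts(track,
      GRanges(chrom[use][hasov], IRanges(ov_s[hasov], ov_e[hasov])))
  body_reads <- gene_reads - ov_reads
  body_bp <- genes$gene_length[use] - ov_w
  prom_bp <- 2 * flank + 1
  out$promoter_reads[use] <- prom_reads
  out$body_reads[use] <- body_reads
  out$promoter_density[use] <- rpm(prom_reads, depth) / (prom_bp / 1000)
  bd <- ifelse(body_bp > 0, rpm(body_reads, depth) / (body_bp / 1000), NA)
  out$body_density[use] <- bd
  pi_ok <- !is.na(bd) & bd > 0
  out$pausing_index[use[pi_ok]] <-
    out$promoter_density[use[pi_ok]] / bd[pi_ok]
  out$status[use][!pi_ok] <- "no_body_signal"
  out
}

## mean coverage of consecutive bins over [s, e] (1-based closed)
.bin_means <- function(v, n_bins) {
  idx <- floor(seq(0, length(v), length.out = n_bins + 1))
  starts <- idx[-length(idx)] + 1
  ends <- idx[-1]
  cs <- c(0, cumsum(v))
  (cs[ends + 1] - cs[starts]) / pmax(ends - starts + 1, 1)
}

#' Meta-gene Pol II profile per gene group
#'
#' Fixed-width flanks (upstream of the TSS, downstream of the TES) in
#' `flank_bin`-bp bins and a length-scaled gene body in `body_bins`
#' equal-fraction bins; minus-strand genes are reversed so all profiles
#' read TSS to TES. Signal is per-base coverage in RPM; the group profile
#' is the per-bin mean over genes.
#'
#' @param track coverage track.
#' @param genes gene `GRanges`.
#' @param groups group label per gene.
#' @param body_bins gene-body bin count.
#' @param upstream,downstream flank sizes in bp.
#' @param flank_bin flank bin width in bp.
#' @return list with `profile` (matrix bins x groups), `bin_coords`
#'   (data.frame `segment`, `position`), `n_genes` per group.
#' @export
metagene_profile <- function(track, genes, groups, body_bins = 100L,
                             upstream = 1000L, downstream = 2000L,
                             flank_bin = 50L) {
  stopifnot(length(groups) == length(genes))
  groups <- as.character(groups)
  if (any(is.na(groups))) stop("NA group label")
  depth <- track_depth(track)
  up_bins <- upstream %/% flank_bin
  dn_bins <- downstream %/% flank_bin
  total_bins <- up_bins + body_bins + dn_bins
  chrom_len <- vapply(track, length, integer(1))
  keep <- width(genes) >= body_bins
  mats <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g & keep)
    if (length(idx) == 0L) stop("group ", g, " has no usable genes")
    acc <- matrix(NA_real_, length(idx), total_bins)
    for (k in seq_along(idx)) {
      i <- idx[k]
      ch <- as.character(seqnames(genes))[i]
      L <- chrom_len[[ch]]
      minus <- as.character(strand(genes))[i] == "-"
      gs <- start(genes)[i]; ge <- end(genes)[i]
      if (!minus) {
        lo <- gs - upstream; hi <- ge + downstream
      } else {
        lo <- gs - downstream; hi <- ge + upstream
      }
      if (lo < 1 || hi > L) next
      v <- as.numeric(Views(track[[ch]], IRanges(lo, hi))[[1]])
      if (minus) v <- rev(v)
      upv <- v[seq_len(upstream)]
      bodyv <- v[upstream + seq_len(ge - gs + 1)]
      dnv <- v[upstream + (ge - gs + 1) + seq_len(downstream)]
      acc[k, ] <- c(.bin_means(upv, up_bins),
                    .bin_means(bodyv, body_bins),
                    .bin_means(dnv, dn_bins)) * 1e6 / depth
    }
    mats[[g]] <- colMeans(acc, na.rm = TRUE)
  }
  profile <- do.call(cbind, mats)
  seg <- c(rep("upstream", up_bins), rep("body", body_bins),
           rep("downstream", dn_bins))
  list(profile = profile,
       bin_coords = data.frame(segment = seg, bin = seq_len(total_bins)),
       n_genes = vapply(unique(groups), function(g)
         sum(groups == g & keep), integer(1)))
}

#' Correlation between binding and Pol II / expression per gene
#'
#' Pearson correlation on `log2(x + pseudocount)` with a t-distribution
#' p-value (the `cor.test` default).
#'
#' @param x,y paired per-gene values (e.g. binding RPM and Pol II body
#'   density); pairs with missing values are dropped.
#' @param pseudocount added before the log transform.
#' @param log log2-transform inputs first.
#' @return list `r`, `p`, `n`.
#' @export
binding_expression_correlation <- function(x, y, pseudocount = 1,
                                           log = TRUE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (log) { x <- log2(x + pseudocount); y <- log2(y + pseudocount) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the vectors")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
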