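## Trimmed-ORF expression quantification, twofold differential-expression
## calls, bound-vs-unbound comparisons, cancer-gene catalog consolidation
## and enrichment.

#' Trimmed ORF length per gene
#'
#' The quantified region is the CDS minus the first 15 codons (45 bp)
#' after the start codon and the last 5 codons (15 bp) before the stop
#' codon, minus any overlap with an optional upstream-ORF mask.
#'
#' @param genes gene `GRanges` with `has_orf`, `cds_start`, `cds_end`.
#' @param uorf_mask optional `GRanges` of regions to exclude.
#' @return integer bp per gene (`NA` for non-coding genes or CDS too
#'   short to survive trimming).
#' @export
trimmed_orf_length <- function(genes, uorf_mask = NULL) {
  n <- length(genes)
  out <- rep(NA_integer_, n)
  ok <- which(genes$has_orf & !is.na(genes$cds_start))
  if (length(ok) == 0L) return(out)
  minus <- as.character(strand(genes))[ok] == "-"
  ts <- ifelse(minus, genes$cds_start[ok] + 15L, genes$cds_start[ok] + 45L)
  te <- ifelse(minus, genes$cds_end[ok] - 45L, genes$cds_end[ok] - 15L)
  valid <- te >= ts
  len <- rep(NA_integer_, length(ok))
  len[valid] <- as.integer(te[valid] - ts[valid] + 1L)
  if (!is.null(uorf_mask) && any(valid)) {
    reg <- GRanges(seqnames(genes)[ok][valid],
                   IRanges(ts[valid], te[valid]))
    ovbp <- vapply(seq_along(reg), function(i) {
      isect <- IRanges::intersect(
        GenomicRanges::ranges(reg[i]),
        GenomicRanges::ranges(uorf_mask[seqnames(uorf_mask) ==
                                          as.character(seqnames(reg))[i]]))
      sum(width(isect))
    }, numeric(1))
    len[valid] <- pmax(len[valid] - as.integer(ovbp), 0L)
    len[valid][len[valid] == 0L] <- NA_integer_
  }
  out[ok] <- len
  out
}

#' Expression records over trimmed ORFs
#'
#' RPKM per condition over the trimmed ORF; a gene is `filtered` for a
#' comparison when it has fewer than `min_reads` raw reads in either
#' condition or no valid quantifiable region. Unfiltered genes get a
#' TAM:EtOH fold change and a twofold DE call via [call_de()].
#'
#' @param counts data.frame with `gene_id`, `reads_EtOH`, `reads_TAM`.
#' @param genes gene `GRanges` matching `counts$gene_id`.
#' @param depths named vector `c(EtOH=, TAM=)` of library depths.
#' @param uorf_mask optional `GRanges` excluded from the ORF.
#' @param min_reads raw-read filter (at least this many in each
#'   condition).
#' @param fold DE fold-change threshold.
#' @return data.frame `gene_id`, `region_bp`, `reads_EtOH`, `reads_TAM`,
#'   `rpkm_EtOH`, `rpkm_TAM`, `fold_change`, `log2fc`, `de_status` in
#'   `{up, down, unchanged, filtered}`.
#' @export
expression_records <- function(counts, genes, depths, uorf_mask = NULL,
                               min_reads = 5L, fold = 2) {
  stopifnot(all(c("gene_id", "reads_EtOH", "reads_TAM") %in%
                  names(counts)),
            all(c("EtOH", "TAM") %in% names(depths)))
  idx <- match(counts$gene_id, genes$gene_id)
  if (anyNA(idx)) stop("counts contain genes absent from the annotation")
  region_bp <- trimmed_orf_length(genes, uorf_mask)[idx]
  rk <- function(reads, depth) reads * 1e9 / (depth * region_bp)
  out <- data.frame(gene_id = counts$gene_id, region_bp = region_bp,
                    reads_EtOH = counts$reads_EtOH,
                    reads_TAM = counts$reads_TAM,
                    stringsAsFactors = FALSE)
  out$rpkm_EtOH <- rk(counts$reads_EtOH, depths[["EtOH"]])
  out$rpkm_TAM <- rk(counts$reads_TAM, depths[["TAM"]])
  filtered <- is.na(region_bp) | counts$reads_EtOH < min_reads |
    counts$reads_TAM < min_reads
  out$fold_change <- ifelse(filtered, NA, out$rpkm_TAM / out$rpkm_EtOH)
  out$log2fc <- log2(out$fold_change)
  out$de_status <- call_de(out$fold_change, fold = fold)
  out$de_status[filtered] <- "filtered"
  out
}

#' Twofold differential-expression calls
#'
#' `up` when the fold change is at least `fold` (inclusive), `down` when
#' at most `1/fold` (inclusive), otherwise `unchanged`; `NA` fold changes
#' give `filtered`.
#'
#' @param fold_change TAM:EtOH ratios.
#' @param fold threshold (default twofold).
#' @return character vector of calls.
#' @export
call_de <- function(fold_change, fold = 2) {
  out <- rep("unchanged", length(fold_change))
  out[!is.na(fold_change) & fold_change >= fold] <- "up"
  out[!is.na(fold_change) & fold_change <= 1 / fold] <- "down"
  out[is.na(fold_change)] <- "filtered"
  out
}

#' Bound versus unbound expression comparison
#'
#' Two-sided Wilcoxon rank-sum tests of log2 RPKM per condition and of
#' the log2 fold change, between genes bound by the factor (target genes)
#' and unbound genes. Filtered genes are excluded from the fold-change
#' comparison (their fold change is undefined, not imputed).
#'
#' @param records data.frame from [expression_records()].
#' @param bound_genes character vector of target gene ids.
#' @param pseudocount added to RPKM before the log.
#' @return data.frame per comparison (`EtOH`, `TAM`, `fold_change`):
#'   group sizes, medians of the compared quantity, `p_value`.
#' @export
bound_vs_unbound <- function(records, bound_genes, pseudocount = 0.1) {
  bound <- records$gene_id %in% bound_genes
  if (!any(bound) || all(bound)) stop("bound or unbound group is empty")
  cmp <- function(vals, usable, label) {
    b <- vals[bound & usable]; u <- vals[!bound & usable]
    if (!length(b) || !length(u)) stop("empty group in ", label)
    data.frame(comparison = label, n_bound = length(b),
               n_unbound = length(u),
               median_bound = median(b), median_unbound = median(u),
               p_value = wilcox_p2(b, u))
  }
  rbind(cmp(log2(records$rpkm_EtOH + pseudocount),
            is.finite(records$rpkm_EtOH), "EtOH"),
        cmp(log2(records$rpkm_TAM + pseudocount),
            is.finite(records$rpkm_TAM), "TAM"),
        cmp(records$log2fc, !is.na(records$log2fc) &
              is.finite(records$log2fc), "fold_change"))
}

#' Consolidate cancer-gene catalogs
#'
#' Takes per-source gene sets annotated as oncogene (ONG) or tumor
#' suppressor (TSG), unions them per role, and labels genes in both role
#' unions as OncoTSG. Idempotent and order-independent.
#'
#' @param sources list of `list(genes = <character>, role = "ONG"|"TSG")`.
#' @return data.frame `gene_id`, `label` in `{ONG, TSG, OncoTSG}`, plus
#'   attribute `counts` (per final label).
#' @export
consolidate_catalogs <- function(sources) {
  roles <- vapply(sources, `[[`, character(1), "role")
  stopifnot(all(roles %in% c("ONG", "TSG")))
  ong <- sort(unique(unlist(lapply(sources[roles == "ONG"], `[[`,
                                   "genes"))))
  tsg <- sort(unique(unlist(lapply(sources[roles == "TSG"], `[[`,
                                   "genes"))))
  both <- intersect(ong, tsg)
  df <- data.frame(gene_id = union(ong, tsg), stringsAsFactors = FALSE)
  df$label <- ifelse(df$gene_id %in% both, "OncoTSG",
                     ifelse(df$gene_id %in% ong, "ONG", "TSG"))
  df <- df[order(df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "counts") <- c(ONG = sum(df$label == "ONG"),
                          TSG = sum(df$label == "TSG"),
                          OncoTSG = sum(df$label == "OncoTSG"))
  df
}

#' Cancer-gene enrichment among target genes
#'
#' For each catalog label (and all cancer genes combined) a 2x2 Fisher
#' exact test of target status versus label over the gene universe, plus
#' the fraction of targets carrying the label and the fraction of label
#' genes that are targets.
#'
#' @param catalog data.frame from [consolidate_catalogs()] (genes absent
#'   from it are NonCancer).
#' @param target_genes character vector, subset of `universe`.
#' @param universe character vector of all genes considered.
#' @return data.frame per label: counts, `odds_ratio`, `p_value`,
#'   `frac_of_targets`, `frac_of_label_targeted`.
#' @export
cancer_enrichment <- function(catalog, target_genes, universe) {
  if (!all(target_genes %in% universe))
    stop("target genes must be a subset of the universe")
  labels <- setNames(rep("NonCancer", length(universe)), universe)
  known <- intersect(catalog$gene_id, universe)
  labels[known] <- catalog$label[match(known, catalog$gene_id)]
  is_target <- universe %in% target_genes
  one <- function(in_label, name) {
    a <- sum(is_target & in_label); b <- sum(is_target & !in_label)
    c <- sum(!is_target & in_label); d <- sum(!is_target & !in_label)
    or <- if (any(c(a, b, c, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    data.frame(label = name, targets_in = a, targets_out = b,
               nontargets_in = c, nontargets_out = d,
               odds_ratio = or,
               p_value = fisher.test(matrix(c(a, b, c, d), 2))$p.value,
               frac_of_targets = a / max(a + b, 1),
               frac_of_label_targeted = a / max(a + c, 1))
  }
  rows <- lapply(c("ONG", "TSG", "OncoTSG"), function(l)
    one(labels == l, l))
  rows[["cancer"]] <- one(labels != "NonCancer", "Cancer")
  do.call(rbind, rows)
}

#' Reference cancer-gene overlap percentages
#'
#' Recomputes, from the reference count table shipped with the package
#' (catalog sizes and per-label target counts for the S100A8/A9
#' target-gene analysis in the ER-Src transformation model), the
#' percentage of target genes that are cancer genes and the percentage of
#' annotated cancer genes that are targets.
#'
#' @param path count table (TSV with columns `label`, `catalog_size`,
#'   `target_count` and a `total_targets` attribute row); defaults to the
#'   table in `inst/extdata`.
#' @return list with `pct_targets_cancer`, `pct_cancer_targeted`,
#'   `n_targets`, `n_cancer_genes`, and the table.
#' @export
cancer_reference_summary <- function(path = system.file(
  "extdata", "cancer_gene_reference_counts.tsv", package = "chipcoact")) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  total_row <- tab$label == "AllTargets"
  stopifnot(sum(total_row) == 1)
  n_targets <- tab$target_count[total_row]
  lab <- tab[!total_row, , drop = FALSE]
  cancer_targets <- sum(lab$target_count)
  n_cancer <- sum(lab$catalog_size)
  list(pct_targets_cancer = 100 * cancer_targets / n_targets,
       pct_cancer_targeted = 100 * cancer_targets / n_cancer,
       n_targets = n_targets, n_cancer_genes = n_cancer,
       table = tab)
}
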