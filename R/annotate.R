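## Chromatin-state classification of peaks, peak-to-gene target mapping,
## and class enrichment against a DNase background.

#' Classify peak summits by chromatin state
#'
#' Summit-centric classification with precedence
#' promoter > enhancer > repressed > uncharacterized: a summit in an
#' H3K4me3 region is a promoter; otherwise in H3K4me1 or H3K27ac an
#' enhancer; otherwise in H3K9me3 or H3K27me3 repressed; otherwise
#' uncharacterized.
#'
#' @param peaks `GRanges` with a `summit` metadata column.
#' @param states named list of mark `GRanges` (`H3K4me3`, `H3K4me1`,
#'   `H3K27ac`, `H3K9me3`, `H3K27me3`; missing marks count as empty).
#' @param precedence class order, highest first.
#' @return factor of classes, parallel to `peaks`, with levels
#'   `promoter`, `enhancer`, `repressed`, `uncharacterized`.
#' @export
classify_peaks <- function(peaks, states,
                           precedence = c("promoter", "enhancer",
                                          "repressed")) {
  marks_for <- list(promoter = "H3K4me3",
                    enhancer = c("H3K4me1", "H3K27ac"),
                    repressed = c("H3K9me3", "H3K27me3"))
  sgr <- summit_granges(peaks)
  cls <- rep("uncharacterized", length(peaks))
  for (cl in rev(precedence)) {
    regions <- lapply(marks_for[[cl]], function(m) states[[m]] %||% GRanges())
    hit <- Reduce(`|`, lapply(regions, function(r) overlapsAny(sgr, r)),
                  accumulate = FALSE, init = rep(FALSE, length(peaks)))
    cls[hit] <- cl
  }
  factor(cls, levels = c(precedence, "uncharacterized"))
}

#' Assign promoter peaks to genes by nearest qualifying TSS
#'
#' A TSS qualifies for a summit if, strand-aware, the summit lies within
#' `upstream` bp upstream to `downstream` bp downstream of the TSS
#' (inclusive bounds) and, when the summit lies downstream of the TSS
#' (towards the gene body), the distance is additionally `< 5 percent` of
#' the gene length. Each peak is assigned to the nearest qualifying TSS
#' by absolute distance; ties go to the lexicographically smaller
#' `gene_id`.
#'
#' @param peaks promoter-classified `GRanges` with `summit`.
#' @param genes gene `GRanges` from [read_gene_table()].
#' @param upstream,downstream window bounds in bp.
#' @param max_gene_frac downstream distance bound as fraction of gene
#'   length.
#' @return data.frame with `peak_idx`, `gene_id`, `distance` (absolute),
#'   `signed_distance` (positive = downstream of TSS); peaks with no
#'   qualifying TSS are absent.
#' @export
assign_promoter_targets <- function(peaks, genes, upstream = 1500L,
                                    downstream = 250L,
                                    max_gene_frac = 0.05) {
  if (length(peaks) == 0L)
    return(data.frame(peak_idx = integer(0), gene_id = character(0),
                      distance = numeric(0), signed_distance = numeric(0)))
  sgr <- summit_granges(peaks)
  plus <- as.character(strand(genes)) == "+"
  win_start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  win_end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  wins <- GRanges(seqnames(genes), IRanges(pmax(1, win_start), win_end))
  ov <- findOverlaps(sgr, wins)
  if (length(ov) == 0L)
    return(data.frame(peak_idx = integer(0), gene_id = character(0),
                      distance = numeric(0), signed_distance = numeric(0)))
  pi <- queryHits(ov); gi <- subjectHits(ov)
  summ <- peaks$summit[pi]
  tss <- genes$tss[gi]
  signed <- ifelse(plus[gi], summ - tss, tss - summ)  # + = into gene body
  ok <- signed <= 0 | signed < max_gene_frac * genes$gene_length[gi]
  ## exact window bounds (findOverlaps already enforces them, but clipped
  ## windows at chromosome start could over-reach; re-check)
  ok <- ok & signed >= -upstream & signed <= downstream
  pi <- pi[ok]; gi <- gi[ok]; signed <- signed[ok]
  if (length(pi) == 0L)
    return(data.frame(peak_idx = integer(0), gene_id = character(0),
                      distance = numeric(0), signed_distance = numeric(0)))
  df <- data.frame(peak_idx = pi, gene_id = genes$gene_id[gi],
                   distance = abs(signed), signed_distance = signed,
                   stringsAsFactors = FALSE)
  df <- df[order(df$peak_idx, df$distance, df$gene_id), ]
  df[!duplicated(df$peak_idx), , drop = FALSE]
}

#' Assign enhancer peaks to genes within a distance window
#'
#' A gene is a target of an enhancer peak if its TSS is within `max_dist`
#' bp of the peak summit (inclusive) or the summit falls inside the gene
#' interval. Many-to-many: one peak may target several genes and vice
#' versa.
#'
#' @param peaks enhancer-classified `GRanges` with `summit`.
#' @param genes gene `GRanges`.
#' @param max_dist TSS distance bound in bp.
#' @return data.frame with `peak_idx`, `gene_id`, `distance`
#'   (|TSS - summit|).
#' @export
assign_enhancer_targets <- function(peaks, genes, max_dist = 50000L) {
  empty <- data.frame(peak_idx = integer(0), gene_id = character(0),
                      distance = numeric(0))
  if (length(peaks) == 0L || length(genes) == 0L) return(empty)
  sgr <- summit_granges(peaks)
  tssgr <- GRanges(seqnames(genes), IRanges(genes$tss, width = 1L))
  wins <- GRanges(seqnames(peaks),
                  IRanges(pmax(1, peaks$summit - max_dist),
                          peaks$summit + max_dist))
  ov1 <- findOverlaps(wins, tssgr)
  ov2 <- findOverlaps(sgr, GRanges(seqnames(genes),
                                   IRanges(start(genes), end(genes))))
  pi <- c(queryHits(ov1), queryHits(ov2))
  gi <- c(subjectHits(ov1), subjectHits(ov2))
  if (length(pi) == 0L) return(empty)
  df <- unique(data.frame(peak_idx = pi, gene_id = genes$gene_id[gi],
                          distance = abs(genes$tss[gi] - peaks$summit[pi]),
                          stringsAsFactors = FALSE))
  df[order(df$peak_idx, df$gene_id), , drop = FALSE]
}

#' Partition target genes into Pr / Eh / Pr+Eh classes
#'
#' @param promoter_targets,enhancer_targets data.frames from the
#'   `assign_*_targets` functions.
#' @return data.frame `gene_id`, `target_class` (`Pr`, `Eh`, `Pr+Eh`).
#' @export
gene_target_classes <- function(promoter_targets, enhancer_targets) {
  pr <- unique(promoter_targets$gene_id)
  eh <- unique(enhancer_targets$gene_id)
  both <- intersect(pr, eh)
  df <- data.frame(gene_id = union(pr, eh), stringsAsFactors = FALSE)
  df$target_class <- ifelse(df$gene_id %in% both, "Pr+Eh",
                            ifelse(df$gene_id %in% pr, "Pr", "Eh"))
  df[order(df$gene_id), , drop = FALSE]
}

#' Chromatin-class enrichment of peaks against a background
#'
#' For every class, a 2x2 Fisher exact test of membership in that class
#' among peaks versus background regions.
#'
#' @param peak_classes,background_classes factors (or characters) over the
#'   same class vocabulary.
#' @return data.frame per class: counts, `odds_ratio` (sample OR,
#'   cross-product with 0.5 correction when a margin is zero), two-sided
#'   `p_value`.
#' @export
class_enrichment <- function(peak_classes, background_classes) {
  if (length(background_classes) == 0L) stop("empty background")
  classes <- union(levels(factor(peak_classes)),
                   levels(factor(background_classes)))
  rows <- lapply(classes, function(cl) {
    a <- sum(peak_classes == cl); b <- sum(peak_classes != cl)
    c <- sum(background_classes == cl); d <- sum(background_classes != cl)
    or <- if (any(c(a, b, c, d) == 0))
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
    else (a * d) / (b * c)
    data.frame(class = cl, peaks_in = a, peaks_out = b,
               background_in = c, background_out = d,
               odds_ratio = or,
               p_value = fisher.test(matrix(c(a, b, c, d), 2))$p.value)
  })
  do.call(rbind, rows)
}
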