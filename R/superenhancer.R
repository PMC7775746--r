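## ROSE-style super-enhancer identification: stitch H3K27ac enhancer
## peaks within 12.5 kb, rank by input-corrected signal, and cut at the
## point where the rescaled signal-vs-rank curve reaches slope 1.

#' Stitch enhancer peaks within a distance
#'
#' Transitive stitching of peaks on the same chromosome whose gap is at
#' most `distance` bp (inclusive). The stitched signal is the sum over
#' constituents of `max(signal - input_signal, 0)`.
#'
#' @param peaks `GRanges` of H3K27ac enhancer peaks (H3K4me3-lacking)
#'   with metadata `signal` (ChIP RPM) and optionally `input_signal`
#'   (depth-scaled input RPM, default 0).
#' @param distance stitching distance in bp.
#' @return `GRanges` of stitched regions with `n_constituents`, `signal`,
#'   and `constituents` (comma-separated indices into `peaks`).
#' @export
stitch_enhancers <- function(peaks, distance = 12500L) {
  if (length(peaks) == 0L) return(GRanges())
  inp <- peaks$input_signal %||% rep(0, length(peaks))
  corrected <- pmax((peaks$signal %||% rep(0, length(peaks))) - inp, 0)
  stitched <- reduce(GRanges(seqnames(peaks),
                             IRanges(start(peaks), end(peaks))),
                     min.gapwidth = distance + 1L)
  ov <- findOverlaps(GRanges(seqnames(peaks),
                             IRanges(start(peaks), end(peaks))),
                     stitched)
  sig <- numeric(length(stitched)); nc <- integer(length(stitched))
  cons <- character(length(stitched))
  for (j in seq_along(stitched)) {
    i <- queryHits(ov)[subjectHits(ov) == j]
    sig[j] <- sum(corrected[i]); nc[j] <- length(i)
    cons[j] <- paste(i, collapse = ",")
  }
  stitched$n_constituents <- nc
  stitched$signal <- sig
  stitched$constituents <- cons
  stitched
}

#' Call super-enhancers by the rescaled-slope criterion
#'
#' Regions are sorted ascending by signal; rank and signal are rescaled
#' to [0, 1]. The cutoff is the point where a line of slope 1 is tangent
#' to the signal-versus-rank curve from below -- the point minimising
#' `y - x` in rescaled units, where the discrete slope of the (convex)
#' curve crosses 1 (on ties the topmost point wins). Regions with signal
#' strictly above the cutoff are super-enhancers. If all signals are
#' equal the curve is flat and no region is called super. The cutoff is
#' invariant under uniform scaling of the signals.
#'
#' @param stitched `GRanges` from [stitch_enhancers()] with `signal`.
#' @return `stitched` with added `rank` (1 = strongest) and `is_super`,
#'   plus attribute `cutoff` (signal units).
#' @export
call_super <- function(stitched) {
  n <- length(stitched)
  if (n < 3L) stop("need at least 3 stitched regions, got ", n)
  s <- stitched$signal
  ord <- order(s)
  ss <- s[ord]
  stitched$rank <- as.integer(rank(-s, ties.method = "first"))
  if (max(ss) == min(ss)) {
    stitched$is_super <- rep(FALSE, n)
    attr(stitched, "cutoff") <- NA_real_
    return(stitched)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (ss - min(ss)) / (max(ss) - min(ss))
  d <- y - x
  cut_idx <- max(which(d == min(d)))
  cutoff <- ss[cut_idx]
  stitched$is_super <- s > cutoff
  attr(stitched, "cutoff") <- cutoff
  stitched
}

#' Assign genes to stitched enhancer regions
#'
#' A gene is assigned to a region if its TSS lies within `max_dist` bp of
#' the nearest region edge (inclusive; zero inside the region) or the
#' gene interval overlaps the region.
#'
#' @param stitched stitched-enhancer `GRanges`.
#' @param genes gene `GRanges` with `tss`.
#' @param max_dist TSS distance bound in bp.
#' @return data.frame `region_idx`, `gene_id`, `distance` (bp from TSS to
#'   nearest region edge, 0 if inside or overlapping).
#' @export
assign_se_genes <- function(stitched, genes, max_dist = 50000L) {
  empty <- data.frame(region_idx = integer(0), gene_id = character(0),
                      distance = numeric(0))
  if (length(stitched) == 0L || length(genes) == 0L) return(empty)
  tssgr <- GRanges(seqnames(genes), IRanges(genes$tss, width = 1L))
  wins <- GRanges(seqnames(stitched),
                  IRanges(pmax(1, start(stitched) - max_dist),
                          end(stitched) + max_dist))
  ov1 <- findOverlaps(wins, tssgr)
  ov2 <- findOverlaps(GRanges(seqnames(stitched),
                              IRanges(start(stitched), end(stitched))),
                      GRanges(seqnames(genes),
                              IRanges(start(genes), end(genes))))
  ri <- c(queryHits(ov1), queryHits(ov2))
  gi <- c(subjectHits(ov1), subjectHits(ov2))
  if (length(ri) == 0L) return(empty)
  tss <- genes$tss[gi]
  d <- pmax(start(stitched)[ri] - tss, tss - end(stitched)[ri], 0)
  df <- unique(data.frame(region_idx = ri, gene_id = genes$gene_id[gi],
                          distance = d, stringsAsFactors = FALSE))
  df[order(df$region_idx, df$gene_id), , drop = FALSE]
}
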