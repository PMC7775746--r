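## Peak calling and processing. The caller is a windowed Poisson test of
## ChIP counts against a depth-scaled input background; the confident-peak
## definition applies the study's triple filter (q <= 1e-7 against input,
## called in >= 2 replicates, >= 5 raw reads in the region) verbatim.

## sliding-window sums of a coverage track: windows start every `step` bp
.window_sums <- function(track, window, step) {
  out <- list()
  for (ch in names(track)) {
    v <- cumsum(as.numeric(track[[ch]]))
    n <- length(v)
    if (n < window) next
    starts <- seq(1L, n - window + 1L, by = step)
    ends <- starts + window - 1L
    sums <- v[ends] - c(0, v)[starts]
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            count = sums)
  }
  do.call(rbind, out)
}

## per-window Poisson upper-tail p-values of ChIP vs depth-scaled input
.window_pvalues <- function(chip, input, window_bp, step_bp) {
  depth_chip <- track_depth(chip)
  depth_input <- track_depth(input)
  if (depth_input <= 0) stop("zero-depth input track: lambda undefined")
  w <- .window_sums(chip, window_bp, step_bp)
  if (is.null(w) || nrow(w) == 0L) return(w)
  wi <- .window_sums(input, window_bp, step_bp)
  input_count <- setNames(wi$count, paste(wi$chrom, wi$start))[
    paste(w$chrom, w$start)]
  input_count[is.na(input_count)] <- 0
  genome_bp <- sum(vapply(chip, length, integer(1)))
  lambda_floor <- depth_chip * window_bp / genome_bp
  w$lambda <- pmax(input_count * (depth_chip / depth_input), lambda_floor)
  w$p <- ppois(w$count - 1, w$lambda, lower.tail = FALSE)
  w
}

#' Call candidate peaks with a windowed Poisson test
#'
#' Slides a window along the genome and tests the ChIP read count against
#' `Poisson(lambda)` where `lambda` is the depth-scaled input count in the
#' same window, floored at the genome-wide mean ChIP rate per window
#' (a local-background floor, so regions with no input coverage are not
#' trivially significant). P-values are upper-tail `P(X >= k)`,
#' BH-corrected over all tested windows; windows with `q <= q_max` that
#' overlap are merged, and the merged region's summit is the position of
#' maximal ChIP coverage (leftmost on ties).
#'
#' @param chip,input coverage tracks on the same chromosome set.
#' @param window_bp,step_bp window geometry (bp); `window_bp >= 50`.
#' @param q_max candidate significance threshold on BH q-values.
#' @return `GRanges` of merged candidate peaks with metadata `summit`,
#'   `count` (ChIP reads in region), `input_count`, `p_value` (best
#'   window p), `q_value` (best window q), `n_windows`.
#' @export
call_candidate_peaks <- function(chip, input, window_bp = 300L,
                                 step_bp = 50L, q_max = 0.01) {
  stopifnot(window_bp >= 50L, step_bp >= 1L)
  w <- .window_pvalues(chip, input, window_bp, step_bp)
  if (is.null(w) || nrow(w) == 0L) return(GRanges())
  p <- w$p
  q <- p.adjust(p, method = "BH")
  sig <- which(q <= q_max)
  if (length(sig) == 0L) return(GRanges())
  wgr <- GRanges(w$chrom[sig], IRanges(w$start[sig], w$end[sig]))
  wgr$p <- p[sig]; wgr$q <- q[sig]
  merged <- reduce(wgr, min.gapwidth = 0L)
  ov <- findOverlaps(wgr, merged)
  pk <- merged
  pk$p_value <- as.numeric(tapply(wgr$p[queryHits(ov)], subjectHits(ov), min))
  pk$q_value <- as.numeric(tapply(wgr$q[queryHits(ov)], subjectHits(ov), min))
  pk$n_windows <- as.integer(table(subjectHits(ov)))
  pk$count <- region_counts(chip, pk)
  pk$input_count <- region_counts(input, pk)
  pk$summit <- vapply(seq_along(pk), function(i)
    max_position(chip[[as.character(seqnames(pk))[i]]],
                 start(pk)[i], end(pk)[i]), integer(1))
  pk
}

#' Apply the confident-peak triple filter
#'
#' Keeps pooled peaks that satisfy all of: BH q-value at most `q_max`
#' (inclusive), region overlapping (by >= 1 bp) a candidate peak in at
#' least `min_replicates` replicate candidate sets, and at least
#' `min_reads` pooled raw reads in the region.
#'
#' @param pooled_peaks `GRanges` from [call_candidate_peaks()] on the
#'   replicate-pooled track (must carry `q_value` and `count`).
#' @param replicate_candidates list (length >= 2) of per-replicate
#'   candidate `GRanges`.
#' @param q_max,min_replicates,min_reads the three filter thresholds.
#' @return filtered `GRanges` with added `n_replicates_supporting`.
#' @export
confident_peaks <- function(pooled_peaks, replicate_candidates,
                            q_max = 1e-7, min_replicates = 2L,
                            min_reads = 5L) {
  if (length(replicate_candidates) < 2L)
    stop("need at least min_replicates = ", min_replicates,
         " replicate candidate sets, got ", length(replicate_candidates))
  if (length(pooled_peaks) == 0L) return(pooled_peaks)
  support <- rowSums(vapply(replicate_candidates, function(cand)
    overlapsAny(pooled_peaks, cand, minoverlap = 1L),
    logical(length(pooled_peaks))))
  pooled_peaks$n_replicates_supporting <- as.integer(support)
  keep <- pooled_peaks$q_value <= q_max &
    support >= min_replicates &
    pooled_peaks$count >= min_reads
  pooled_peaks[keep]
}

#' Call confident peaks from replicate ChIP tracks
#'
#' Convenience wrapper: pools the replicate tracks, calls candidates on
#' the pool and on each replicate, then applies [confident_peaks()].
#'
#' @param chip_replicates list of >= 2 coverage tracks.
#' @param input matched input coverage track.
#' @param q_max,min_replicates,min_reads confident-peak thresholds.
#' @param window_bp,step_bp caller geometry.
#' @param candidate_q per-replicate candidate threshold (reproducibility
#'   support is assessed at this looser level).
#' @return `GRanges` of confident peaks.
#' @export
call_confident_peaks <- function(chip_replicates, input, q_max = 1e-7,
                                 min_replicates = 2L, min_reads = 5L,
                                 window_bp = 300L, step_bp = 50L,
                                 candidate_q = 0.01) {
  if (length(chip_replicates) < 2L)
    stop("need at least ", min_replicates, " replicates")
  pooled <- pool_tracks(chip_replicates)
  pooled_peaks <- call_candidate_peaks(pooled, input, window_bp, step_bp,
                                       q_max = candidate_q)
  cands <- lapply(chip_replicates, call_candidate_peaks, input = input,
                  window_bp = window_bp, step_bp = step_bp,
                  q_max = candidate_q)
  confident_peaks(pooled_peaks, cands, q_max = q_max,
                  min_replicates = min_replicates, min_reads = min_reads)
}

#' Refine peak summits on pooled coverage
#'
#' Re-estimates each peak's summit from a (typically replicate- and
#' factor-pooled) coverage track: the read-count centroid in a window of
#' `half_window` bp around the argmax of smoothed coverage. For a
#' symmetric binding-site read distribution the centroid is an unbiased
#' summit estimator with standard error `spread / sqrt(reads)`, far more
#' precise than a per-base argmax.
#'
#' @param track pooled coverage track.
#' @param peaks `GRanges` with `summit`.
#' @param half_window centroid window half-width in bp; choose it to
#'   cover the whole binding-site read distribution so the centroid does
#'   not inherit the argmax jitter through window truncation.
#' @param iterations centroid re-centering passes.
#' @return `peaks` with updated `summit`.
#' @export
refine_summits <- function(track, peaks, half_window = 150L,
                           iterations = 2L) {
  if (length(peaks) == 0L) return(peaks)
  chr <- as.character(seqnames(peaks))
  out <- peaks$summit
  for (i in seq_along(peaks)) {
    r <- track[[chr[i]]]
    if (is.null(r)) next
    center <- max_position(r, start(peaks)[i], end(peaks)[i])
    for (it in seq_len(iterations)) {
      lo <- max(1L, center - half_window)
      hi <- min(length(r), center + half_window)
      v <- as.numeric(Views(r, IRanges(lo, hi))[[1L]])
      tot <- sum(v)
      if (tot == 0) break
      center <- as.integer(round(sum((lo:hi) * v) / tot))
    }
    out[i] <- center
  }
  peaks$summit <- out
  peaks
}

#' Merge peak sets at >= 1 bp overlap
#'
#' Transitive closure of the >= 1 bp overlap relation (half-open abutment
#' does not merge). The merged interval is the union span; the merged
#' summit is the summit of the constituent with the largest `signal`
#' metadata value (leftmost summit on ties; if no `signal` column is
#' present the leftmost constituent summit is used).
#'
#' @param ... peak `GRanges` objects (or a single list of them), each with
#'   a `summit` metadata column.
#' @return merged `GRanges` with `summit` and `n_constituents`.
#' @export
merge_peak_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !methods::is(sets[[1]], "GRanges")) sets <- sets[[1]]
  all <- do.call(c, unname(lapply(sets, function(g) {
    out <- GRanges(seqnames(g), IRanges(start(g), end(g)))
    out$summit <- g$summit %||% floor((start(g) + end(g)) / 2)
    out$signal <- g$signal %||% rep(0, length(g))
    out
  })))
  if (length(all) == 0L) return(GRanges())
  merged <- reduce(all, min.gapwidth = 0L)
  ov <- findOverlaps(all, merged)
  sm <- integer(length(merged)); nc <- integer(length(merged))
  for (j in seq_along(merged)) {
    i <- queryHits(ov)[subjectHits(ov) == j]
    nc[j] <- length(i)
    best <- i[all$signal[i] == max(all$signal[i])]
    sm[j] <- min(all$summit[best])
  }
  merged$summit <- sm
  merged$n_constituents <- nc
  merged
}

#' Replicate-pooled RPM signal of regions
#'
#' @param tracks list of replicate coverage tracks (pooled by summation).
#' @param regions `GRanges`.
#' @return numeric RPM per region (pooled counts x 1e6 / pooled depth).
#' @export
peak_signal_rpm <- function(tracks, regions) {
  pooled <- pool_tracks(tracks)
  rpm(region_counts(pooled, regions), track_depth(pooled))
}

#' Combined two-factor signal and factor correlation
#'
#' The combined signal is the arithmetic mean of the two factors'
#' replicate-pooled RPM; the correlation is Pearson on
#' `log2(RPM + pseudocount)`.
#'
#' @param a8_rpm,a9_rpm per-peak RPM vectors on a common merged universe.
#' @param pseudocount added before the log transform.
#' @return list with `combined` (numeric vector), `r`, `p`, `n`.
#' @export
combined_signal <- function(a8_rpm, a9_rpm, pseudocount = 1) {
  if (length(a8_rpm) == 0L) stop("empty peak universe")
  stopifnot(length(a8_rpm) == length(a9_rpm))
  ct <- cor.test(log2(a8_rpm + pseudocount), log2(a9_rpm + pseudocount))
  list(combined = (a8_rpm + a9_rpm) / 2,
       r = unname(ct$estimate), p = ct$p.value, n = length(a8_rpm))
}

#' Differential binding between conditions on a merged peak universe
#'
#' Counts are pooled over replicates (and factors, if tracks from both are
#' supplied) per condition. The fold change is
#' `(TAM RPM + c) / (EtOH RPM + c)` with pseudocount `c` in RPM units.
#' Significance is an exact conditional binomial test of the pooled TAM
#' count against the depth ratio, BH-corrected.
#'
#' @param universe merged peak `GRanges`.
#' @param tam_tracks,etoh_tracks lists of coverage tracks per condition.
#' @param pseudocount RPM pseudocount.
#' @param alpha BH q-value threshold for the significance flag.
#' @return `GRanges` copy of `universe` with `count_etoh`, `count_tam`,
#'   `rpm_etoh`, `rpm_tam`, `fold_change`, `log2fc`, `p_value`, `q_value`,
#'   `significant`.
#' @export
differential_binding <- function(universe, tam_tracks, etoh_tracks,
                                 pseudocount = 0.5, alpha = 0.05) {
  tam <- pool_tracks(tam_tracks); etoh <- pool_tracks(etoh_tracks)
  d_t <- track_depth(tam); d_e <- track_depth(etoh)
  stopifnot(d_t > 0, d_e > 0)
  k_t <- region_counts(tam, universe)
  k_e <- region_counts(etoh, universe)
  r_t <- rpm(k_t, d_t); r_e <- rpm(k_e, d_e)
  fc <- (r_t + pseudocount) / (r_e + pseudocount)
  p0 <- d_t / (d_t + d_e)
  p <- vapply(seq_along(universe), function(i) {
    n <- k_t[i] + k_e[i]
    if (n == 0) return(1)
    binom.test(k_t[i], n, p = p0)$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- universe
  out$count_etoh <- k_e; out$count_tam <- k_t
  out$rpm_etoh <- r_e; out$rpm_tam <- r_t
  out$fold_change <- fc; out$log2fc <- log2(fc)
  out$p_value <- p; out$q_value <- q
  out$significant <- q <= alpha
  out
}
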