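#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- findOverlaps countOverlaps reduce resize
#' @importFrom IRanges IRanges Views viewSums subsetByOverlaps overlapsAny
#' @importFrom S4Vectors Rle runValue runLength queryHits subjectHits
#'   RleList DataFrame
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
#'   "subseq<-" writeXStringSet readDNAStringSet
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
#' @importFrom stats ppois rpois rnorm runif rbinom p.adjust fisher.test
#'   wilcox.test binom.test cor cor.test median rexp rlnorm setNames ks.test
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total mapped reads of a coverage track
#'
#' A coverage track is a named list (or `RleList`) of integer run-length
#' encoded vectors of per-base read-start counts, one per chromosome.
#'
#' @param track coverage track (`RleList` or list of `Rle`).
#' @return total read count (numeric scalar).
#' @export
track_depth <- function(track) {
  sum(vapply(track, function(r) sum(as.numeric(runValue(r)) * runLength(r)),
             numeric(1)))
}

#' Read counts of a coverage track in a set of regions
#'
#' Positions beyond the recorded end of a chromosome count as zero; regions
#' on chromosomes absent from the track count as zero.
#'
#' @param track coverage track.
#' @param gr `GRanges` of regions.
#' @return numeric vector of raw read counts, parallel to `gr`.
#' @export
region_counts <- function(track, gr) {
  out <- numeric(length(gr))
  if (length(gr) == 0L) return(out)
  chr <- as.character(seqnames(gr))
  for (ch in unique(chr)) {
    i <- which(chr == ch)
    if (is.null(track[[ch]])) next
    r <- track[[ch]]
    n <- length(r)
    s <- pmax(start(gr)[i], 1L)
    e <- pmin(end(gr)[i], n)
    ok <- s <= e
    if (any(ok)) {
      v <- Views(r, IRanges(s[ok], e[ok]))
      out[i[ok]] <- viewSums(v)
    }
  }
  out
}

#' Reads-per-million normalisation
#'
#' @param counts raw read counts.
#' @param depth library depth (total mapped reads).
#' @return counts scaled to reads per million.
#' @export
rpm <- function(counts, depth) {
  stopifnot(depth > 0)
  counts * 1e6 / depth
}

#' Pool coverage tracks by per-base summation
#'
#' @param tracks list of coverage tracks (chromosomes unioned; shorter
#'   chromosomes zero-padded).
#' @return pooled coverage track.
#' @export
pool_tracks <- function(tracks) {
  stopifnot(length(tracks) >= 1L)
  chroms <- unique(unlist(lapply(tracks, names)))
  out <- lapply(chroms, function(ch) {
    rs <- Filter(Negate(is.null), lapply(tracks, `[[`, ch))
    n <- max(vapply(rs, length, integer(1)))
    acc <- Rle(0L, n)
    for (r in rs) {
      if (length(r) < n) r <- c(r, Rle(0L, n - length(r)))
      acc <- acc + r
    }
    acc
  })
  names(out) <- chroms
  out
}

## two-sided Wilcoxon rank-sum p; fully tied samples carry no evidence
## against the null, so a degenerate (NaN) statistic maps to p = 1
wilcox_p2 <- function(a, b) {
  p <- suppressWarnings(wilcox.test(a, b)$p.value)
  if (is.nan(p) || is.na(p)) 1 else p
}

## position (1-based) of maximum coverage in [s, e]; leftmost on ties.
## With smooth_hw > 0 the maximised quantity is the read count in a
## centered window of half-width smooth_hw (point read-start counts are
## too noisy to place a summit at base resolution).
max_position <- function(r, s, e, smooth_hw = 25L) {
  s <- max(1L, s); e <- min(length(r), e)
  if (smooth_hw == 0L) {
    v <- as.integer(Views(r, IRanges(s, e))[[1L]])
    return(s + which.max(v) - 1L)
  }
  lo <- max(1L, s - smooth_hw); hi <- min(length(r), e + smooth_hw)
  v <- as.numeric(Views(r, IRanges(lo, hi))[[1L]])
  cs <- c(0, cumsum(v))
  pos <- s:e
  a <- pmax(pos - smooth_hw, lo) - lo + 1L
  b <- pmin(pos + smooth_hw, hi) - lo + 1L
  sums <- cs[b + 1L] - cs[a]
  pos[which.max(sums)]
}

## summit positions as width-1 GRanges
summit_granges <- function(peaks) {
  stopifnot(!is.null(peaks$summit))
  GRanges(seqnames(peaks), IRanges(peaks$summit, width = 1L))
}
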