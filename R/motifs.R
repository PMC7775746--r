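## PWM scanning around peak summits, motif-density profiles, and
## motif-stratified differential binding.

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

## integer codes of a sequence; non-ACGT (e.g. N) -> NA
.seq_codes <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "")[[1]]
  unname(.BASE_CODE[ch])
}

## log2-odds score matrix of a pwm (4 x L); an NA base contributes 0
.pwm_lo <- function(pwm) log2(pwm$prob / pwm$background)

## scores of every offset of `codes` against a 4 x L log-odds matrix
.scan_scores <- function(codes, lo) {
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(numeric(0))
  n_off <- n - L + 1L
  sc <- numeric(n_off)
  for (j in seq_len(L)) {
    col <- lo[, j]
    v <- col[codes[j:(j + n_off - 1L)]]
    v[is.na(v)] <- 0  # N positions score with background probability
    sc <- sc + v
  }
  sc
}

#' Scan a sequence window with a PWM on both strands
#'
#' The log-odds score of a match is `sum(log2(p_base / bg_base))` over
#' positions; positions with ambiguous bases (N) contribute 0 (background
#' probability). Minus-strand matches are scored against the
#' reverse-complemented matrix, so a hit and its reverse complement score
#' identically on opposite strands. Hits are matches with score at least
#' the threshold.
#'
#' @param seq `DNAString` or character sequence window.
#' @param pwm a `pwm` object.
#' @param threshold score threshold in bits (default: the PWM's own
#'   `score_threshold`, 80 percent of its maximum score).
#' @return data.frame `start` (1-based match start), `center`
#'   (`start + floor(L/2)`), `strand`, `score`.
#' @export
scan_pwm <- function(seq, pwm, threshold = NULL) {
  threshold <- threshold %||% pwm$score_threshold
  codes <- .seq_codes(seq)
  L <- ncol(pwm$prob)
  if (length(codes) < L)
    return(data.frame(start = integer(0), center = integer(0),
                      strand = character(0), score = numeric(0)))
  lo <- .pwm_lo(pwm)
  lo_rc <- lo[4:1, ncol(lo):1, drop = FALSE]  # reverse complement matrix
  fwd <- .scan_scores(codes, lo)
  rev <- .scan_scores(codes, lo_rc)
  hits_f <- which(fwd >= threshold)
  hits_r <- which(rev >= threshold)
  df <- data.frame(
    start = c(hits_f, hits_r),
    center = c(hits_f, hits_r) + floor(L / 2),
    strand = c(rep("+", length(hits_f)), rep("-", length(hits_r))),
    score = c(fwd[hits_f], rev[hits_r]))
  df[order(df$start, df$strand), , drop = FALSE]
}

#' Motif density around peak summits
#'
#' Counts PWM hit centers at every offset in summit +/- `half_window`
#' across peaks, normalised per covered offset (windows clipped at
#' chromosome edges cover fewer offsets).
#'
#' @param genome `DNAStringSet` keyed by chromosome.
#' @param peaks `GRanges` with `summit`.
#' @param pwm a `pwm` object.
#' @param half_window profile half-width in bp.
#' @param threshold score threshold (default the PWM's).
#' @return data.frame `offset` (-half_window..half_window), `hits`,
#'   `n_covered`, `density` (hits per peak at that offset).
#' @export
motif_density_profile <- function(genome, peaks, pwm, half_window = 200L,
                                  threshold = NULL) {
  L <- ncol(pwm$prob)
  offs <- (-half_window):half_window
  hits <- integer(length(offs))
  covered <- integer(length(offs))
  pad <- L  # scan margin so hits centered at the window edge are seen
  for (i in seq_along(peaks)) {
    ch <- as.character(seqnames(peaks))[i]
    s0 <- peaks$summit[i]
    lo <- max(1L, s0 - half_window - pad)
    hi <- min(length(genome[[ch]]), s0 + half_window + pad)
    win_cov <- pmax(s0 + offs, 1L) == (s0 + offs) &
      (s0 + offs) <= length(genome[[ch]])
    covered <- covered + win_cov
    h <- scan_pwm(subseq(genome[[ch]], lo, hi), pwm, threshold)
    if (nrow(h) == 0L) next
    centers <- lo + h$center - 1L - s0  # offset from summit
    centers <- centers[abs(centers) <= half_window]
    if (length(centers))
      hits <- hits + tabulate(centers + half_window + 1L,
                              nbins = length(offs))
  }
  data.frame(offset = offs, hits = hits, n_covered = covered,
             density = ifelse(covered > 0, hits / covered, NA))
}

#' Motif hits within a window of every peak summit
#'
#' @param genome `DNAStringSet`.
#' @param peaks `GRanges` with `summit`.
#' @param pwms named list of `pwm` objects.
#' @param window half-width around the summit in bp (hit centers within
#'   `summit +/- window` count).
#' @return logical matrix peaks x motifs (presence/absence).
#' @export
peak_motif_matrix <- function(genome, peaks, pwms, window = 50L) {
  out <- matrix(FALSE, length(peaks), length(pwms),
                dimnames = list(NULL, names(pwms)))
  for (m in names(pwms)) {
    L <- ncol(pwms[[m]]$prob)
    for (i in seq_along(peaks)) {
      ch <- as.character(seqnames(peaks))[i]
      s0 <- peaks$summit[i]
      lo <- max(1L, s0 - window - L)
      hi <- min(length(genome[[ch]]), s0 + window + L)
      h <- scan_pwm(subseq(genome[[ch]], lo, hi), pwms[[m]])
      if (nrow(h) == 0L) next
      centers <- lo + h$center - 1L - s0
      out[i, m] <- any(abs(centers) <= window)
    }
  }
  out
}

#' Stratify binding fold changes by motif presence
#'
#' Groups are inclusive: a peak belongs to a combination group if every
#' motif in the set has at least one hit within the summit window
#' (additional motifs allowed). "Other" is the set of peaks carrying none
#' of the motifs mentioned in any combination. Each group's log2 fold
#' changes are compared with Other by a two-sided Wilcoxon rank-sum test.
#'
#' @param log2fc per-peak log2 binding fold change (TAM:EtOH).
#' @param motif_matrix logical peaks x motifs matrix from
#'   [peak_motif_matrix()].
#' @param combos named list of character vectors of motif names; by
#'   default every single motif in the matrix.
#' @return data.frame `group`, `n`, `median_log2fc`, `p_value`, `q_value`
#'   (BH over the non-Other groups), with an `Other` reference row
#'   (`p_value = NA`).
#' @export
stratify_fold_changes <- function(log2fc, motif_matrix, combos = NULL) {
  stopifnot(length(log2fc) == nrow(motif_matrix))
  if (is.null(combos)) {
    combos <- as.list(colnames(motif_matrix))
    names(combos) <- colnames(motif_matrix)
  }
  used <- unique(unlist(combos))
  miss <- setdiff(used, colnames(motif_matrix))
  if (length(miss)) stop("unknown motifs: ", paste(miss, collapse = ", "))
  other <- rowSums(motif_matrix[, used, drop = FALSE]) == 0
  if (!any(other)) stop("empty Other group: no reference peaks")
  rows <- lapply(names(combos), function(g) {
    inset <- rowSums(motif_matrix[, combos[[g]], drop = FALSE]) ==
      length(combos[[g]])
    n <- sum(inset)
    p <- if (n > 0) wilcox_p2(log2fc[inset], log2fc[other]) else NA_real_
    data.frame(group = g, n = n,
               median_log2fc = if (n > 0) median(log2fc[inset]) else NA,
               p_value = p)
  })
  df <- do.call(rbind, rows)
  df$q_value <- p.adjust(df$p_value, method = "BH")
  rbind(df, data.frame(group = "Other", n = sum(other),
                       median_log2fc = median(log2fc[other]),
                       p_value = NA, q_value = NA))
}
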