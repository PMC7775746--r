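## Independent brute-force oracles used to cross-check the analysis
## routines. These deliberately avoid the code paths they validate.

## two-sided Fisher p: sum of hypergeometric probabilities of all tables
## with the observed margins whose probability does not exceed the
## observed table's (with the same relative tolerance stats::fisher.test
## uses for this comparison)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## two-sided exact Wilcoxon rank-sum p by full enumeration of splits
wilcox_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

## Poisson upper tail P(X >= k) by term-wise summation
poisson_tail_oracle <- function(k, lambda, terms = 2000L) {
  if (k <= 0) return(1)
  sum(stats::dpois(seq(k, k + terms), lambda))
}

## transitive closure of >= 1 bp overlap on intervals (1-based closed),
## by union-find
merge_oracle <- function(starts, ends) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && starts[i] <= ends[j] && starts[j] <= ends[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- lapply(unique(roots), function(r) {
    i <- which(roots == r)
    c(min(starts[i]), max(ends[i]))
  })
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

## all-pairs promoter assignment oracle (strand-aware window + 5% rule,
## nearest TSS, lexicographic tie-break)
promoter_assign_oracle <- function(summits, gene_df, upstream = 1500,
                                   downstream = 250, frac = 0.05) {
  out <- data.frame(peak_idx = integer(0), gene_id = character(0))
  for (p in seq_along(summits)) {
    best <- NULL
    for (g in seq_len(nrow(gene_df))) {
      tss <- gene_df$tss[g]
      signed <- if (gene_df$strand[g] == "+") summits[p] - tss
                else tss - summits[p]
      if (signed < -upstream || signed > downstream) next
      if (signed > 0 && !(signed < frac * gene_df$length[g])) next
      cand <- data.frame(gene_id = gene_df$gene_id[g], d = abs(signed))
      if (is.null(best) || cand$d < best$d ||
          (cand$d == best$d && cand$gene_id < best$gene_id)) best <- cand
    }
    if (!is.null(best))
      out <- rbind(out, data.frame(peak_idx = p, gene_id = best$gene_id))
  }
  out
}

## all-pairs enhancer assignment oracle
enhancer_assign_oracle <- function(summits, gene_df, max_dist = 50000) {
  out <- data.frame(peak_idx = integer(0), gene_id = character(0))
  for (p in seq_along(summits)) for (g in seq_len(nrow(gene_df))) {
    hit <- abs(gene_df$tss[g] - summits[p]) <= max_dist ||
      (summits[p] >= gene_df$start[g] && summits[p] <= gene_df$end[g])
    if (hit)
      out <- rbind(out, data.frame(peak_idx = p,
                                   gene_id = gene_df$gene_id[g]))
  }
  out
}

## all-pairs stitched-region gene assignment oracle
se_assign_oracle <- function(reg_df, gene_df, max_dist = 50000) {
  out <- data.frame(region_idx = integer(0), gene_id = character(0))
  for (r in seq_len(nrow(reg_df))) for (g in seq_len(nrow(gene_df))) {
    d <- max(reg_df$start[r] - gene_df$tss[g],
             gene_df$tss[g] - reg_df$end[r], 0)
    ovl <- gene_df$start[g] <= reg_df$end[r] &&
      reg_df$start[r] <= gene_df$end[g]
    if (d <= max_dist || ovl)
      out <- rbind(out, data.frame(region_idx = r,
                                   gene_id = gene_df$gene_id[g]))
  }
  out
}

## naive per-position PWM scan (forward strand only)
scan_oracle <- function(seq_chars, prob, background) {
  L <- ncol(prob)
  n <- length(seq_chars)
  vapply(seq_len(n - L + 1), function(s) {
    sum(vapply(seq_len(L), function(j) {
      b <- match(seq_chars[s + j - 1], c("A", "C", "G", "T"))
      if (is.na(b)) 0 else log2(prob[b, j] / background[b])
    }, numeric(1)))
  }, numeric(1))
}

## all permutations of 1..n (row per permutation)
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}
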