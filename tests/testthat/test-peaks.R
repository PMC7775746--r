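test_that("window Poisson p-values match term-wise tail summation", {
  ## ChIP = 50 reads in a window with scaled lambda = 5
  expect_equal(ppois(50 - 1, 5, lower.tail = FALSE),
               poisson_tail_oracle(50, 5), tolerance = 1e-12)
  for (k in c(0, 1, 3, 10, 40)) for (lam in c(0.5, 5, 20))
    expect_equal(ppois(k - 1, lam, lower.tail = FALSE),
                 poisson_tail_oracle(k, lam), tolerance = 1e-10,
                 label = sprintf("k=%d lambda=%g", k, lam))
  ## zero ChIP reads can never be significant
  expect_equal(ppois(-1, 5, lower.tail = FALSE), 1)
})

test_that("the caller recovers a strong planted site and nothing else", {
  set.seed(1)
  n <- 50000L
  lam <- rep(0.02, n)
  lam[10000:10300] <- 1        # 50x enrichment, ~300 expected reads
  chip <- setNames(list(S4Vectors::Rle(rpois(n, lam))), "chrS")
  input <- setNames(list(S4Vectors::Rle(rpois(n, 0.02))), "chrS")
  pk <- call_candidate_peaks(chip, input, q_max = 1e-7)
  expect_equal(length(pk), 1L)
  expect_true(start(pk) < 10300 && end(pk) > 10000)
  expect_true(abs(pk$summit - 10150) < 150)
  expect_error(call_candidate_peaks(chip, toy_track(n, list())),
               "zero-depth")
})

test_that("confident-peak triple filter is conjunctive with inclusive bounds", {
  mk <- function(s, e, q, count) {
    gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(s, e))
    gr$q_value <- q; gr$count <- count
    gr$summit <- as.integer((s + e) / 2)
    gr
  }
  pooled <- c(mk(100, 200, 1e-8, 4),    # fails read filter
              mk(300, 400, 1e-8, 100),  # in 1/2 replicates only
              mk(500, 600, 1e-6, 100),  # fails q
              mk(700, 800, 1e-7, 100))  # q boundary: kept
  reps <- list(c(mk(100, 200, 1e-8, 4), mk(700, 800, 1e-7, 50),
                 mk(300, 400, 1e-8, 60), mk(500, 600, 1e-6, 60)),
               c(mk(100, 200, 1e-8, 4), mk(700, 800, 1e-7, 50),
                 mk(500, 600, 1e-6, 60)))
  out <- confident_peaks(pooled, reps)
  expect_equal(start(out), 700)
  expect_equal(out$n_replicates_supporting, 2L)
  expect_error(confident_peaks(pooled, reps[1]), "replicate")

  ## monotone: relaxing any threshold never removes a peak
  base <- confident_peaks(pooled, reps)
  for (relax in list(c(1e-6, 2, 5), c(1e-7, 1, 5), c(1e-7, 2, 3))) {
    more <- confident_peaks(pooled, reps, q_max = relax[1],
                            min_replicates = relax[2],
                            min_reads = relax[3])
    expect_true(all(start(base) %in% start(more)))
  }
})

test_that("peak merging follows >=1 bp overlap with transitive closure", {
  ## BED [100,200) + [199,300) share one base -> merged
  a <- toy_peaks(150); a <- GenomicRanges::GRanges("chrS",
                                                   IRanges::IRanges(101, 200))
  a$summit <- 150L
  b <- GenomicRanges::GRanges("chrS", IRanges::IRanges(200, 300))
  b$summit <- 250L
  m <- merge_peak_sets(list(a, b))
  expect_equal(length(m), 1L)
  expect_equal(c(start(m), end(m)), c(101, 300))

  ## half-open abutment ([100,200) + [200,300)) does not merge
  b2 <- GenomicRanges::GRanges("chrS", IRanges::IRanges(201, 300))
  b2$summit <- 250L
  expect_equal(length(merge_peak_sets(list(a, b2))), 2L)

  ## chain A-B, B-C merges all three even though A, C are disjoint
  ch <- list(GenomicRanges::GRanges("chrS", IRanges::IRanges(1, 100)),
             GenomicRanges::GRanges("chrS", IRanges::IRanges(90, 200)),
             GenomicRanges::GRanges("chrS", IRanges::IRanges(190, 300)))
  for (i in seq_along(ch)) ch[[i]]$summit <- as.integer(start(ch[[i]]) + 5)
  m3 <- merge_peak_sets(ch)
  expect_equal(length(m3), 1L)

  ## summit comes from the constituent with the largest signal
  a$signal <- 1; b$signal <- 9
  expect_equal(merge_peak_sets(list(a, b))$summit, 250L)
})

test_that("merging agrees with a union-find oracle and is idempotent", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 40
    s <- sample(1:2000, n)
    e <- s + sample(10:120, n, replace = TRUE)
    pk <- GenomicRanges::GRanges("chrS", IRanges::IRanges(s, e))
    pk$summit <- as.integer((s + e) %/% 2)
    m <- merge_peak_sets(list(pk))
    oracle <- merge_oracle(s, e)
    expect_equal(cbind(start(m), end(m)), unname(oracle))
    ## idempotent and order-independent
    m2 <- merge_peak_sets(list(m))
    expect_equal(start(m2), start(m))
    perm <- sample(n)
    m3 <- merge_peak_sets(list(pk[perm]))
    expect_equal(start(m3), start(m))
  }
})

test_that("combined signal averages factors and reports their correlation", {
  x <- c(1, 4, 9, 16, 25)
  cs <- combined_signal(x, x)
  expect_equal(cs$combined, x)
  expect_equal(cs$r, 1)
  expect_error(combined_signal(numeric(0), numeric(0)), "empty")
  set.seed(3)
  a <- rlnorm(400); b <- rlnorm(400)
  expect_lt(abs(combined_signal(a, b)$r), 0.15)  # independent signals
})

test_that("differential binding matches the exact conditional binomial", {
  u <- GenomicRanges::GRanges("chrS", IRanges::IRanges(101, 200))
  u$summit <- 150L
  tam <- toy_track(1000, list(c(101, 200, 1L)))   # 100 reads in region
  etoh <- toy_track(1000, list(c(101, 200, 1L)))
  d <- differential_binding(u, list(tam), list(etoh))
  expect_equal(d$fold_change, 1)                  # equal counts and depth

  ## TAM 40 vs EtOH 10 at equal depth: conditional binomial k=40, n=50
  tam2 <- toy_track(4000, list(c(101, 140, 1L), c(1000, 3959, 1L)))
  etoh2 <- toy_track(4000, list(c(101, 110, 1L), c(1000, 3989, 1L)))
  d2 <- differential_binding(u, list(tam2), list(etoh2))
  expect_equal(track_depth(tam2), track_depth(etoh2))
  manual <- binom.test(40, 50, 0.5)$p.value
  ## oracle: exact enumeration of the binomial two-sided p
  probs <- dbinom(0:50, 50, 0.5)
  oracle <- sum(probs[probs <= probs[41] * (1 + 1e-7)])
  expect_equal(d2$p_value, manual)
  expect_equal(manual, oracle, tolerance = 1e-12)
})
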