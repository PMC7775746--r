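test_that("consensus scores at the maximum and hits both strands", {
  pw <- default_pwms()$AP1           # consensus TGACTCA
  h <- scan_pwm("TGACTCA", pw)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$score, pw$max_score)
  expect_equal(h$center, 1 + 3)
  ## reverse complement scores identically on the minus strand
  h2 <- scan_pwm("TGAGTCA", pw)      # revcomp of TGACTCA
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, pw$max_score)
})

test_that("scanning equals the naive per-position oracle on random sequence", {
  set.seed(9)
  pw <- default_pwms()$CREB
  seqc <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  seqs <- paste(seqc, collapse = "")
  got <- scan_pwm(seqs, pw, threshold = -Inf)
  fwd <- got[got$strand == "+", ]
  want <- scan_oracle(seqc, pw$prob, pw$background)
  expect_equal(fwd$score, want, tolerance = 1e-12)
  ## minus strand equals scanning the reverse complement forward
  rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[seqc])
  want_rc <- rev(scan_oracle(unname(rc), pw$prob, pw$background))
  expect_equal(got$score[got$strand == "-"], want_rc, tolerance = 1e-12)
  ## N positions contribute the background (zero bits)
  hN <- scan_pwm("TGACGTCA", pw, threshold = -Inf)
  hN2 <- scan_pwm("NGACGTCA", pw, threshold = -Inf)
  delta <- log2(pw$prob[4, 1] / pw$background[4])
  expect_equal(hN2$score[hN2$strand == "+"],
               hN$score[hN$strand == "+"] - delta, ignore_attr = TRUE)
})

test_that("density profile is an indicator for a single planted hit", {
  set.seed(10)
  bg <- paste(sample(c("A", "C"), 1001, replace = TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrS = bg))
  pw <- default_pwms()$AP1
  ## plant consensus with center at summit + 37
  summit <- 500L
  s0 <- summit + 37 - 3
  Biostrings::subseq(genome[[1]], s0, s0 + 6) <- Biostrings::DNAString("TGACTCA")
  d <- motif_density_profile(genome, toy_peaks(summit), pw,
                             half_window = 200)
  expect_equal(d$offset[d$hits > 0], 37)
  expect_equal(sum(d$hits), 1)
  ## profile sums to total hits / peak count
  expect_equal(sum(d$density, na.rm = TRUE), 1)
})

test_that("stratification matches exact rank-sum enumeration", {
  lfc <- c(1.2, 1.3, 1.4, 0.9, 1.0, 1.1)
  mm <- matrix(c(rep(TRUE, 3), rep(FALSE, 3)), ncol = 1,
               dimnames = list(NULL, "AP1"))
  out <- stratify_fold_changes(lfc, mm)
  ap1 <- out[out$group == "AP1", ]
  expect_equal(ap1$n, 3)
  expect_equal(ap1$p_value, wilcox_oracle(lfc[1:3], lfc[4:6]))
  expect_equal(ap1$p_value, 0.1)  # C(6,3) = 20 splits, extreme both ways

  ## identical values in both groups give p = 1
  same <- stratify_fold_changes(rep(1, 6), mm)
  expect_equal(same$p_value[same$group == "AP1"], 1)

  ## empty Other is an error; combos must name known motifs
  mm_all <- matrix(TRUE, 6, 1, dimnames = list(NULL, "AP1"))
  expect_error(stratify_fold_changes(lfc, mm_all), "Other")
  expect_error(stratify_fold_changes(lfc, mm, combos = list(X = "X")),
               "unknown")

  ## inclusive combination semantics and ordering stability
  m2 <- cbind(AP1 = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
              CREB = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  both <- stratify_fold_changes(lfc, m2,
                                combos = list(AP1_CREB = c("AP1", "CREB")))
  expect_equal(both$n[both$group == "AP1_CREB"], 2)
  perm <- c(4, 2, 6, 1, 3, 5)
  out_p <- stratify_fold_changes(lfc[perm], m2[perm, , drop = FALSE],
                                 combos = list(AP1_CREB = c("AP1", "CREB")))
  expect_equal(out_p$median_log2fc, both$median_log2fc)
})

test_that("wilcoxon implementation agrees with full-split enumeration", {
  set.seed(12)
  for (rep in 1:8) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    x <- round(rnorm(n1), 2); y <- round(rnorm(n2) + 0.5, 2)
    if (anyDuplicated(c(x, y))) next      # exact test needs no ties
    expect_equal(suppressWarnings(wilcox.test(x, y)$p.value),
                 wilcox_oracle(x, y), tolerance = 1e-12,
                 label = sprintf("n1=%d n2=%d rep=%d", n1, n2, rep))
  }
})
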