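test_that("uniform coverage gives pausing index 1; all-promoter gives NA", {
  genes <- toy_genes(data.frame(gene_id = "g1", chrom = "chrS",
                                strand = "+", start = 5000, end = 15000))
  uni <- toy_track(20000, list(c(1, 20000, 2L)))
  m <- pol2_gene_metrics(uni, genes)
  expect_equal(m$pausing_index, 1)
  expect_equal(m$status, "ok")

  ## all reads in the promoter window: PI is missing, not infinite
  prom_only <- toy_track(20000, list(c(4750, 5250, 5L)))
  m2 <- pol2_gene_metrics(prom_only, genes)
  expect_true(is.na(m2$pausing_index))
  expect_equal(m2$status, "no_body_signal")
})

test_that("pausing index is scale-invariant and genes are filtered", {
  genes <- toy_genes(data.frame(gene_id = c("g1", "gshort", "gedge"),
                                chrom = "chrS", strand = "+",
                                start = c(5000, 17000, 100),
                                end = c(15000, 17200, 2000)))
  set.seed(2)
  v <- rpois(20000, 0.5); v[4750:5250] <- v[4750:5250] + rpois(501, 3)
  tr <- setNames(list(S4Vectors::Rle(as.integer(v))), "chrS")
  tr3 <- setNames(list(S4Vectors::Rle(as.integer(v * 3L))), "chrS")
  m <- pol2_gene_metrics(tr, genes)
  m3 <- pol2_gene_metrics(tr3, genes)
  expect_equal(m$pausing_index[1], m3$pausing_index[1])
  expect_equal(m$status, c("ok", "short_gene", "edge_gene"))
  ## densities additive: promoter + body reads = reads in gene plus the
  ## upstream half of the window
  full <- region_counts(tr, GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(4750, 15000)))
  expect_equal(m$promoter_reads[1] + m$body_reads[1], full)
})

test_that("planted pausing indices are recovered at adequate depth", {
  sim <- simulate_genome(small_config(21))
  pe <- simulate_pol2_and_expression(sim)
  m <- pol2_gene_metrics(pe$pol2$EtOH, sim$genes)
  mm <- merge(m, sim$truth, by = "gene_id")
  ok <- mm$status == "ok" & mm$body_reads >= 200
  relerr <- abs(mm$pausing_index.x[ok] - mm$pausing_index.y[ok]) /
    mm$pausing_index.y[ok]
  expect_gt(sum(ok), 50)
  expect_lt(median(relerr), 0.25)
  ## planted PI around 1 estimates within [0.8, 1.25] for covered genes
  near1 <- ok & abs(mm$pausing_index.y - 1) < 0.05
  if (any(near1))
    expect_true(all(mm$pausing_index.x[near1] >= 0.7 &
                      mm$pausing_index.x[near1] <= 1.4))
})

test_that("meta-gene profiles are flat for uniform signal and mirror strands", {
  genes <- toy_genes(data.frame(gene_id = c("gp", "gm"), chrom = "chrS",
                                strand = c("+", "-"),
                                start = c(5000, 30000),
                                end = c(10000, 35000)))
  uni <- toy_track(50000, list(c(1, 50000, 3L)))
  pr <- metagene_profile(uni, genes, groups = c("A", "B"))
  expect_equal(max(pr$profile) - min(pr$profile), 0)

  ## a mirrored bump: +strand gene with signal near TSS vs -strand gene
  ## with signal near its (right-side) TSS give identical profiles
  bump <- toy_track(50000, list(c(5000, 5499, 4L),   # + gene TSS side
                                c(34501, 35000, 4L))) # - gene TSS side
  p2 <- metagene_profile(bump, genes, groups = c("A", "B"))
  expect_equal(p2$profile[, "A"], p2$profile[, "B"])
  expect_error(metagene_profile(uni, genes, groups = c(NA, "B")), "NA")
})

test_that("binding correlation matches hand computation and permutations", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(binding_expression_correlation(x, 2 * x, log = FALSE)$r, 1)
  expect_error(binding_expression_correlation(x, rep(1, 5), log = FALSE),
               "variance")
  set.seed(8)
  a <- rnorm(5); b <- rnorm(5)
  got <- binding_expression_correlation(a, b, log = FALSE)
  expect_equal(got$r, cor(a, b))
  ## permutation cross-check of the p-value at small n: the exact
  ## permutation p of |r| brackets the t-based p loosely
  perms <- combinat_perms(5)
  r_obs <- abs(cor(a, b))
  r_all <- apply(perms, 1, function(i) abs(cor(a, b[i])))
  p_perm <- mean(r_all >= r_obs - 1e-12)
  expect_lt(abs(p_perm - got$p), 0.2)
})
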