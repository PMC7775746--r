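states_toy <- function() {
  g <- function(s, e) GenomicRanges::GRanges("chrS",
                                             IRanges::IRanges(s, e))
  list(H3K4me3 = g(100, 200), H3K27ac = g(150, 400),
       H3K4me1 = g(350, 500), H3K9me3 = g(600, 700),
       H3K27me3 = g(650, 800))
}

test_that("summit classification follows the precedence order", {
  st <- states_toy()
  pk <- toy_peaks(c(180, 380, 660, 900))
  cls <- classify_peaks(pk, st)
  ## 180 is in H3K4me3 AND H3K27ac -> promoter wins
  expect_equal(as.character(cls),
               c("promoter", "enhancer", "repressed", "uncharacterized"))
  expect_equal(sum(prop.table(table(cls))), 1)
})

test_that("promoter assignment applies window and 5% rules inclusively", {
  genes <- toy_genes(data.frame(
    gene_id = c("gLong", "gShort", "gMinus"),
    chrom = "chrS", strand = c("+", "+", "-"),
    start = c(10000, 40000, 70000),
    end = c(20000, 43000, 80000)))   # lengths 10001, 3001, 10001

  ## summit 200 bp downstream of a 10 kb gene: 200 < 500 -> assigned
  a <- assign_promoter_targets(toy_peaks(10200), genes)
  expect_equal(a$gene_id, "gLong")
  ## same offset into a 3 kb gene: 200 >= 150 -> rejected
  expect_equal(nrow(assign_promoter_targets(toy_peaks(40200), genes)), 0)
  ## exactly at TSS - 1500 (upstream bound) -> assigned
  a2 <- assign_promoter_targets(toy_peaks(10000 - 1500), genes)
  expect_equal(a2$gene_id, "gLong")
  ## one bp beyond -> not assigned
  expect_equal(nrow(assign_promoter_targets(toy_peaks(10000 - 1501),
                                            genes)), 0)
  ## minus-strand gene: upstream window is to the right of the TSS
  a3 <- assign_promoter_targets(toy_peaks(80000 + 1500), genes)
  expect_equal(a3$gene_id, "gMinus")
  a4 <- assign_promoter_targets(toy_peaks(80000 - 200), genes)
  expect_equal(a4$gene_id, "gMinus")  # 200 bp into the body, < 500
})

test_that("promoter assignment equals the all-pairs oracle on random sets", {
  set.seed(11)
  for (rep in 1:3) {
    ng <- 50
    starts <- sort(sample(seq(5000, 4e5, by = 100), ng))
    lens <- sample(2000:20000, ng, replace = TRUE)
    gdf <- data.frame(gene_id = sprintf("g%02d", 1:ng), chrom = "chrS",
                      strand = sample(c("+", "-"), ng, TRUE),
                      start = starts, end = starts + lens)
    gdf$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
    gdf$length <- lens + 1
    genes <- toy_genes(gdf)
    summits <- sample(seq(4000, 4.3e5), 120)
    got <- assign_promoter_targets(toy_peaks(summits), genes)
    want <- promoter_assign_oracle(summits, gdf)
    expect_equal(got[, c("peak_idx", "gene_id")], want,
                 ignore_attr = TRUE)
    ## pure: result independent of peak ordering
    perm <- sample(length(summits))
    got2 <- assign_promoter_targets(toy_peaks(summits[perm]), genes)
    expect_setequal(paste(perm[got2$peak_idx], got2$gene_id),
                    paste(got$peak_idx, got$gene_id))
  }
})

test_that("enhancer assignment honours the 50 kb and overlap clauses", {
  genes <- toy_genes(data.frame(
    gene_id = c("gNear", "gFar"), chrom = "chrS", strand = "+",
    start = c(100000, 300000), end = c(110000, 400000)))
  ## 49,999 bp and exactly 50,000 bp from the TSS: both assigned
  expect_true("gNear" %in%
                assign_enhancer_targets(toy_peaks(100000 - 49999),
                                        genes)$gene_id)
  expect_true("gNear" %in%
                assign_enhancer_targets(toy_peaks(100000 - 50000),
                                        genes)$gene_id)
  expect_false("gNear" %in%
                 assign_enhancer_targets(toy_peaks(100000 - 50001),
                                         genes)$gene_id)
  ## summit inside the gene body 80 kb from its TSS: overlap clause
  a <- assign_enhancer_targets(toy_peaks(380000), genes)
  expect_true("gFar" %in% a$gene_id)

  set.seed(5)
  gdf <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chrS",
                    strand = "+",
                    start = sort(sample(seq(1e4, 8e5, 100), 30)))
  gdf$end <- gdf$start + sample(2000:30000, 30, TRUE)
  gdf$tss <- gdf$start
  genes2 <- toy_genes(gdf)
  summits <- sample(seq(1e4, 8e5), 60)
  got <- assign_enhancer_targets(toy_peaks(summits), genes2)
  want <- enhancer_assign_oracle(summits, gdf)
  expect_equal(got[, c("peak_idx", "gene_id")],
               want[order(want$peak_idx, want$gene_id), ],
               ignore_attr = TRUE)
})

test_that("gene target classes partition into Pr / Eh / Pr+Eh", {
  pr <- data.frame(peak_idx = 1:2, gene_id = c("a", "b"))
  eh <- data.frame(peak_idx = 3:4, gene_id = c("b", "c"))
  tc <- gene_target_classes(pr, eh)
  expect_equal(setNames(tc$target_class, tc$gene_id),
               c(a = "Pr", b = "Pr+Eh", c = "Eh"))
})

test_that("class enrichment Fisher tests match hypergeometric enumeration", {
  ## identical class distributions: OR = 1, p = 1
  cls <- rep(c("promoter", "enhancer"), c(30, 70))
  res <- class_enrichment(cls, rep(cls, 2))
  expect_equal(res$odds_ratio, c(1, 1))
  expect_equal(res$p_value, c(1, 1))
  expect_error(class_enrichment(cls, character(0)), "background")

  ## the [[30,70],[10,90]] worked table
  p_pkg <- fisher.test(matrix(c(30, 70, 10, 90), 2))$p.value
  expect_equal(p_pkg, fisher_oracle(30, 70, 10, 90), tolerance = 1e-9)
})
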