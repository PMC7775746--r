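toy_coding_genes <- function() {
  toy_genes(data.frame(
    gene_id = c("g300", "gshort", "gminus"),
    chrom = "chrS", strand = c("+", "+", "-"),
    start = c(1000, 5000, 9000), end = c(1500, 5100, 9999),
    cds_start = c(1100, 5010, 9100), cds_end = c(1399, 5069, 9699)))
}

test_that("ORF trimming removes 15 start and 5 stop codons", {
  genes <- toy_coding_genes()
  len <- trimmed_orf_length(genes)
  expect_equal(len[1], 300 - 45 - 15)   # 300 bp CDS -> 240 bp
  expect_true(is.na(len[2]))            # 60 bp CDS vanishes
  expect_equal(len[3], 600 - 45 - 15)   # strand-aware trimming
  ## uORF mask subtracts its overlap
  mask <- GenomicRanges::GRanges("chrS", IRanges::IRanges(1145, 1244))
  expect_equal(trimmed_orf_length(genes, mask)[1], 240 - 100)
})

test_that("RPKM, read filter and twofold calls follow the definitions", {
  genes <- toy_genes(data.frame(gene_id = "g1", chrom = "chrS",
                                strand = "+", start = 1, end = 2000,
                                cds_start = 101, cds_end = 1160))
  expect_equal(trimmed_orf_length(genes), 1000)
  counts <- data.frame(gene_id = "g1", reads_EtOH = 10, reads_TAM = 20)
  rec <- expression_records(counts, genes,
                            depths = c(EtOH = 1e6, TAM = 1e6))
  expect_equal(rec$rpkm_EtOH, 10)   # 10 reads, 1 kb, 1e6 depth
  expect_equal(rec$rpkm_TAM, 20)
  expect_equal(rec$de_status, "up") # ratio exactly 2.0 is up (inclusive)

  counts$reads_TAM <- 19
  expect_equal(expression_records(counts, genes,
                                  c(EtOH = 1e6, TAM = 1e6))$de_status,
               "unchanged")          # 1.9-fold
  counts$reads_EtOH <- 4
  expect_equal(expression_records(counts, genes,
                                  c(EtOH = 1e6, TAM = 1e6))$de_status,
               "filtered")           # < 5 raw reads

  ## de_status partition is exhaustive
  set.seed(13)
  many <- data.frame(gene_id = rep("g1", 50),
                     reads_EtOH = rpois(50, 6), reads_TAM = rpois(50, 6))
  recs <- expression_records(many, genes, c(EtOH = 1e6, TAM = 1e6))
  expect_equal(sum(table(recs$de_status)), 50)
  expect_true(all(recs$de_status %in%
                    c("up", "down", "unchanged", "filtered")))
  expect_true(all(recs$de_status[recs$reads_EtOH < 5 |
                                   recs$reads_TAM < 5] == "filtered"))
})

test_that("bound-vs-unbound comparisons use exact small-sample Wilcoxon", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:6),
                    rpkm_EtOH = c(2, 4, 8, 16, 32, 64),
                    rpkm_TAM = c(2, 4, 8, 16, 32, 64),
                    log2fc = c(4, 5, 6, 1, 2, 3))
  out <- bound_vs_unbound(rec, c("g1", "g2", "g3"))
  fc <- out[out$comparison == "fold_change", ]
  expect_equal(fc$p_value, wilcox_oracle(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(fc$p_value, 0.1)
  expect_error(bound_vs_unbound(rec, character(0)), "empty")
  expect_error(bound_vs_unbound(rec, rec$gene_id), "empty")
})

test_that("catalog consolidation matches set algebra and is idempotent", {
  src <- list(list(genes = c("g1", "g2"), role = "ONG"),
              list(genes = c("g1", "g3"), role = "TSG"))
  cat1 <- consolidate_catalogs(src)
  expect_equal(setNames(cat1$label, cat1$gene_id),
               c(g1 = "OncoTSG", g2 = "ONG", g3 = "TSG"))
  expect_equal(attr(cat1, "counts"),
               c(ONG = 1L, TSG = 1L, OncoTSG = 1L))
  ## disjoint sources keep their sizes
  dis <- consolidate_catalogs(list(
    list(genes = c("a", "b"), role = "ONG"),
    list(genes = c("c"), role = "TSG")))
  expect_equal(unname(attr(dis, "counts")), c(2L, 1L, 0L))
  ## order independence and idempotence against a set-algebra oracle
  set.seed(14)
  pool <- sprintf("g%03d", 1:60)
  srcs <- lapply(1:5, function(i)
    list(genes = sample(pool, 20), role = sample(c("ONG", "TSG"), 1)))
  c1 <- consolidate_catalogs(srcs)
  c2 <- consolidate_catalogs(rev(srcs))
  expect_identical(c1, c2)
  ong <- Reduce(union, lapply(Filter(function(s) s$role == "ONG", srcs),
                              `[[`, "genes"), character(0))
  tsg <- Reduce(union, lapply(Filter(function(s) s$role == "TSG", srcs),
                              `[[`, "genes"), character(0))
  expect_setequal(c1$gene_id[c1$label == "OncoTSG"], intersect(ong, tsg))
  expect_setequal(c1$gene_id[c1$label == "ONG"], setdiff(ong, tsg))
})

test_that("cancer enrichment Fisher tests match enumeration and fractions", {
  universe <- sprintf("g%03d", 1:200)
  catalog <- data.frame(gene_id = universe[1:40],
                        label = rep(c("ONG", "TSG", "OncoTSG"),
                                    c(15, 20, 5)))
  targets <- universe[c(1:30, 101:140)]   # cancer-heavy targets
  res <- cancer_enrichment(catalog, targets, universe)
  cancer <- res[res$label == "Cancer", ]
  expect_equal(cancer$targets_in, 30)
  expect_equal(cancer$frac_of_targets, 30 / 70)
  expect_equal(cancer$frac_of_label_targeted, 30 / 40)
  expect_equal(cancer$p_value,
               fisher_oracle(30, 40, 10, 120), tolerance = 1e-9)
  ## targets = universe: every fraction equals prevalence, p = 1
  all_t <- cancer_enrichment(catalog, universe, universe)
  expect_equal(all_t$p_value, rep(1, 4))
  expect_error(cancer_enrichment(catalog, c("nope"), universe), "subset")
})

test_that("fisher.test equals hypergeometric enumeration across tables", {
  set.seed(15)
  for (rep in 1:60) {
    n <- sample(8:200, 1)
    a <- sample(0:min(n, 30), 1); b <- sample(0:40, 1)
    c <- sample(0:40, 1); d <- max(n - a - b - c, 0)
    p <- fisher.test(matrix(c(a, b, c, d), 2))$p.value
    expect_equal(p, fisher_oracle(a, b, c, d), tolerance = 1e-8,
                 label = sprintf("table %d %d %d %d", a, b, c, d))
  }
})
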