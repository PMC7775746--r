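## Shared fixtures. The default-scale study run is expensive, so it is
## simulated once per test session and reused by every file that needs
## it.

.fixtures <- new.env(parent = emptyenv())

## default-scale study + full pipeline (the study conditions)
default_run <- function() {
  if (is.null(.fixtures$run))
    .fixtures$run <- suppressMessages(
      run_pipeline(run_config(sim = sim_config(seed = 101))))
  .fixtures$run
}

## reduced problem size for multi-seed property loops: a proportional
## shrink of the default study (about half the genome, genes and sites),
## preserving gene/site density so bound and unbound genes both occur
small_config <- function(seed, ...) {
  sim_config(seed = seed, n_chroms = 2, chrom_length = 1.2e6,
             n_genes = 140,
             n_sites = c(promoter = 56L, enhancer = 84L,
                         repressed = 12L, null = 36L),
             n_background_enhancers = 70L, n_superenhancers = 6L,
             n_dnase = 700L, ...)
}

## null configuration: no planted binding sites at all
null_config <- function(seed) {
  sim_config(seed = seed, n_chroms = 1, chrom_length = 1e6, n_genes = 60,
             n_sites = c(promoter = 0L, enhancer = 0L, repressed = 0L,
                         null = 0L),
             n_background_enhancers = 40L, n_superenhancers = 3L,
             n_dnase = 300L)
}

## tiny deterministic coverage track from spans (1-based closed)
toy_track <- function(len, spans = list(), chrom = "chrS") {
  v <- integer(len)
  for (s in spans) v[s[1]:s[2]] <- v[s[1]:s[2]] + as.integer(s[3])
  setNames(list(S4Vectors::Rle(as.integer(v))), chrom)
}

## toy gene GRanges from a data frame with gene_id, chrom, strand,
## start, end (1-based closed) and optional cds bounds
toy_genes <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  gr$gene_id <- df$gene_id
  gr$tss <- ifelse(df$strand == "+", df$start, df$end)
  gr$tes <- ifelse(df$strand == "+", df$end, df$start)
  gr$has_orf <- if (!is.null(df$cds_start)) !is.na(df$cds_start)
                else rep(FALSE, nrow(df))
  gr$cds_start <- if (!is.null(df$cds_start)) df$cds_start else NA_integer_
  gr$cds_end <- if (!is.null(df$cds_end)) df$cds_end else NA_integer_
  gr$gene_length <- df$end - df$start + 1L
  gr
}

## peaks GRanges from summit vector (width-1 regions unless given)
toy_peaks <- function(summits, chrom = "chrS", width = 1L) {
  hw <- (width - 1L) %/% 2L
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(summits - hw,
                                                summits + hw))
  gr$summit <- as.integer(summits)
  gr
}
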