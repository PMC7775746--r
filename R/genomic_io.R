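## Readers/writers for the external formats the pipeline touches.
## Convention: files are in their native coordinate systems (BED family is
## 0-based half-open); everything is converted to GRanges (1-based closed)
## at this boundary and stays GRanges inside the package.

.split_fields <- function(lines) strsplit(lines, "[ \t]+")

#' Read a BED6 or narrowPeak file
#'
#' narrowPeak summit offsets (column 10, relative to the region start) are
#' converted to absolute 1-based summit coordinates in the `summit`
#' metadata column; an offset of -1 (summit not called) yields the region
#' midpoint.
#'
#' @param path file path.
#' @param dialect `"bed6"` or `"narrowPeak"`.
#' @return `GRanges` in file order with metadata columns `name`, `score`
#'   (and `signal`, `p_value`, `q_value`, `summit` for narrowPeak).
#' @export
read_bed <- function(path, dialect = c("bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GRanges())
  need <- if (dialect == "bed6") 6L else 10L
  fields <- .split_fields(lines)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < need)
      stop(sprintf("line %d: expected %d fields, got %d", i, need, length(f)))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("line %d: non-numeric coordinates", i))
    if (e <= s)
      stop(sprintf("line %d: end (%s) <= start (%s)", i, f[3], f[2]))
    if (s < 0) stop(sprintf("line %d: negative start", i))
    if (dialect == "narrowPeak") {
      off <- suppressWarnings(as.numeric(f[10]))
      if (is.na(off)) stop(sprintf("line %d: non-numeric summit offset", i))
      if (off >= e - s)
        stop(sprintf("line %d: summit offset %d >= region length %d",
                     i, off, e - s))
    }
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  start0 <- as.numeric(m[, 2]); end0 <- as.numeric(m[, 3])
  strand <- if (need >= 6L) m[, 6] else "."
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GRanges(m[, 1], IRanges(start0 + 1, end0), strand = strand)
  gr$name <- m[, 4]
  gr$score <- suppressWarnings(as.numeric(m[, 5]))
  if (dialect == "narrowPeak") {
    gr$signal <- as.numeric(m[, 7])
    gr$p_value <- as.numeric(m[, 8])
    gr$q_value <- as.numeric(m[, 9])
    off <- as.numeric(m[, 10])
    summit <- ifelse(off >= 0, start0 + off + 1,
                     floor((start0 + 1 + end0) / 2))
    gr$summit <- as.integer(summit)
  }
  gr
}

#' Write peaks as narrowPeak
#'
#' Column 9 carries -log10 of the q-value; column 10 the summit offset from
#' the region start (0-based).
#'
#' @param peaks `GRanges` with `summit` and optionally `q_value` metadata.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  q <- peaks$q_value %||% rep(NA_real_, length(peaks))
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = peaks$name %||% sprintf("peak_%d", seq_along(peaks)),
    score = 0L,
    strand = ".",
    signal = peaks$signal %||% 0,
    p = -log10(pmax(peaks$p_value %||% rep(1, length(peaks)), 1e-300)),
    q = -log10(pmax(q, 1e-300)),
    summit = (peaks$summit %||% floor((start(peaks) + end(peaks)) / 2)) -
      start(peaks))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED6
#' @param gr `GRanges`; `name`/`score` metadata used when present.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  st <- as.character(strand(gr)); st[st == "*"] <- "."
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L, end = end(gr),
    name = gr$name %||% sprintf("r%d", seq_along(gr)),
    score = gr$score %||% 0, strand = st)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a refGene-style gene table
#'
#' Expects a tab-separated file with a header naming at least
#' `name`, `chrom`, `strand`, `txStart`, `txEnd`, `cdsStart`, `cdsEnd`
#' (UCSC refGene convention: 0-based half-open spans). One row becomes one
#' gene record; duplicate names with distinct TSSs are kept as separate
#' records (no isoform collapsing).
#'
#' The TSS is the first transcribed base (`txStart` for + genes, the last
#' base for - genes); `cdsStart == cdsEnd` marks a non-coding transcript
#' (`has_orf = FALSE`, CDS bounds `NA`).
#'
#' @param path file path.
#' @return `GRanges` with metadata `gene_id`, `tss`, `tes`, `cds_start`,
#'   `cds_end` (1-based closed), `has_orf`, `gene_length`.
#' @export
read_gene_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "strand", "txStart", "txEnd",
            "cdsStart", "cdsEnd")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (!all(tab$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         paste(unique(setdiff(tab$strand, c("+", "-"))), collapse = ", "))
  if (any(tab$txEnd <= tab$txStart)) stop("txEnd <= txStart")
  gr <- GRanges(tab$chrom, IRanges(tab$txStart + 1, tab$txEnd),
                strand = tab$strand)
  plus <- tab$strand == "+"
  gr$gene_id <- tab$name
  gr$tss <- ifelse(plus, tab$txStart + 1, tab$txEnd)
  gr$tes <- ifelse(plus, tab$txEnd, tab$txStart + 1)
  noncoding <- tab$cdsStart == tab$cdsEnd
  gr$has_orf <- !noncoding
  gr$cds_start <- ifelse(noncoding, NA_integer_, tab$cdsStart + 1)
  gr$cds_end <- ifelse(noncoding, NA_integer_, tab$cdsEnd)
  gr$gene_length <- width(gr)
  gr
}

#' Write a gene table in refGene-style layout
#' @param genes `GRanges` as returned by [read_gene_table()].
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  cs <- ifelse(genes$has_orf, genes$cds_start - 1L, start(genes) - 1L)
  ce <- ifelse(genes$has_orf, genes$cds_end, start(genes) - 1L)
  df <- data.frame(name = genes$gene_id,
                   chrom = as.character(seqnames(genes)),
                   strand = as.character(strand(genes)),
                   txStart = start(genes) - 1L, txEnd = end(genes),
                   cdsStart = cs, cdsEnd = ce)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file into a coverage track
#'
#' Spans must be non-overlapping and non-negative; unspecified positions
#' are zero. Values must be integer read counts.
#'
#' @param path file path.
#' @param seqlengths optional named chromosome lengths; tracks are padded
#'   with zeros to these lengths (otherwise each chromosome ends at its
#'   last covered base).
#' @return named list of integer `Rle`, one per chromosome.
#' @export
read_coverage <- function(path, seqlengths = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "value"),
                    stringsAsFactors = FALSE)
  if (any(tab$value < 0)) stop("negative coverage value")
  if (any(tab$end <= tab$start)) stop("empty or inverted span")
  out <- list()
  for (ch in unique(tab$chrom)) {
    sub <- tab[tab$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping spans on ", ch)
    n <- if (!is.null(seqlengths[[ch]])) seqlengths[[ch]] else max(sub$end)
    vec <- integer(n)
    for (i in seq_len(nrow(sub)))
      vec[(sub$start[i] + 1):sub$end[i]] <- as.integer(sub$value[i])
    out[[ch]] <- Rle(vec)
  }
  out
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; adjacent equal-value spans are merged (run-length
#' canonical form), so `read_coverage(write_coverage(t))` reproduces `t`
#' up to trailing zeros (pass `seqlengths` to recover those).
#'
#' @param track coverage track (named list of integer `Rle`).
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track)) {
    r <- track[[ch]]
    if (any(runValue(r) < 0)) stop("negative coverage value on ", ch)
    ends <- cumsum(runLength(r))
    starts <- ends - runLength(r)   # 0-based starts
    keep <- runValue(r) != 0
    if (!any(keep)) next
    df <- data.frame(ch, starts[keep], ends[keep], runValue(r)[keep])
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read position weight matrices in JASPAR PFM format
#'
#' Accepts the JASPAR text layout: a `>ID name` header followed by four
#' rows `A [ n1 n2 ... ]` (brackets and row letters optional). Counts are
#' converted to per-column probabilities after adding a pseudocount to
#' every cell.
#'
#' @param path file path.
#' @param pseudocount added to every count cell before normalisation.
#' @param background base frequencies (A, C, G, T).
#' @param score_frac default hit threshold as a fraction of the maximum
#'   achievable log-odds score.
#' @return list of `pwm` objects (see [new_pwm()]).
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4),
                        score_frac = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no JASPAR headers found")
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    hdr <- sub("^>\\s*", "", lines[heads[k]])
    id <- strsplit(trimws(hdr), "[ \t]+")[[1]][1]
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != 4L)
      stop("motif ", id, ": expected 4 matrix rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ \t]*[ACGTacgt][ \t:|]*", "", l)
      l <- gsub("[", " ", l, fixed = TRUE)
      l <- gsub("]", " ", l, fixed = TRUE)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1L)
      stop("motif ", id, ": rows of unequal length")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- new_pwm(id, counts, pseudocount = pseudocount,
                         background = background, score_frac = score_frac)
  }
  out
}

#' Construct a position weight matrix object
#'
#' @param motif_id identifier string.
#' @param counts 4 x L count (or probability) matrix, rows A, C, G, T.
#' @param pseudocount added per cell before column normalisation.
#' @param background base frequencies summing to 1.
#' @param score_frac default hit threshold as a fraction of the maximum
#'   log-odds score (log2 odds vs background, summed over positions).
#' @return object of class `pwm`: list with `motif_id`, `prob` (4 x L),
#'   `background`, `score_threshold` (bits), `max_score`.
#' @export
new_pwm <- function(motif_id, counts, pseudocount = 1,
                    background = rep(0.25, 4), score_frac = 0.8) {
  stopifnot(nrow(counts) == 4L, ncol(counts) >= 4L,
            abs(sum(background) - 1) < 1e-6)
  prob <- apply(counts + pseudocount, 2, function(col) col / sum(col))
  stopifnot(all(abs(colSums(prob) - 1) < 1e-6))
  rownames(prob) <- c("A", "C", "G", "T")
  lo <- log2(prob / background)
  max_score <- sum(apply(lo, 2, max))
  structure(list(motif_id = motif_id, prob = prob, background = background,
                 score_threshold = score_frac * max_score,
                 max_score = max_score),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: %d positions, max score %.2f bits, threshold %.2f\n",
              x$motif_id, ncol(x$prob), x$max_score, x$score_threshold))
  invisible(x)
}

#' Write PWMs in JASPAR PFM format (probabilities scaled to counts)
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @param scale counts total per column.
#' @export
write_jaspar <- function(pwms, path, scale = 100) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$motif_id), con)
    m <- round(p$prob * scale)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(m[b, ], collapse = " ")), con)
  }
  invisible(path)
}
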