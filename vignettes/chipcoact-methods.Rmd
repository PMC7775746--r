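---
title: "Methods: integrative analysis of a chromatin-associated coactivator"
author: "chipcoact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative analysis of a chromatin-associated coactivator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model system

`chipcoact` implements the computational pipeline used to characterise a
chromatin-associated transcriptional coactivator — modelled on S100A8/A9
in the tamoxifen-inducible ER-Src breast transformation system, where
"EtOH" denotes the nontransformed control and "TAM" the transformed
condition. The pipeline covers: confident ChIP-seq peak definition,
chromatin-state classification of peaks, peak-to-gene target mapping,
Pol II density and pausing metrics, ROSE-style super-enhancer calling,
PWM motif scanning with motif-stratified differential binding,
trimmed-ORF expression quantification, and cancer-gene catalog
consolidation and enrichment. A seeded synthetic-study generator
produces a complete miniature study with recorded ground truth so every
stage can be validated by parameter recovery.

## Coordinate conventions

All file formats are read in their native conventions (BED family
0-based half-open, refGene txStart 0-based) and converted at the I/O
boundary to `GRanges` (1-based closed), the canonical container of the
Bioconductor stack, which provides the interval algebra (overlap,
reduction, nearest queries) used throughout. The boundary semantics of
the analyses are unaffected and are pinned by tests: half-open abutment
is not an overlap, the TSS of a minus-strand gene is its last
transcribed base, and all window bounds below are inclusive.

## Peak calling and the confident-peak filter

The candidate caller slides a `window_bp = 300` window in `step_bp = 50`
steps and computes a Poisson upper-tail p-value for the ChIP read count
against `lambda` equal to the depth-scaled input count in the same
window, floored at the genome-wide mean ChIP rate per window. The floor
plays the role of a local-background guard: windows with no input
coverage are not trivially significant. P-values are BH-corrected over
all tested windows; overlapping significant windows are merged.

Confident peaks apply three conjunctive filters, all inclusive at their
boundaries: pooled q-value at most `1e-7` against the matched input,
region called in at least 2 replicates (overlap of at least 1 bp with a
per-replicate candidate, assessed at a looser candidate threshold of
q <= 0.01, since replicate support is a reproducibility statement rather
than a second significance test), and at least 5 raw reads in the
region. The confident set is monotone in all three thresholds.

Summits: per-base read-start counts are too noisy to place a summit at
base resolution (the argmax of raw counts jitters by about +/-10 bp at
realistic depths), so the summit is the argmax of the read count in a
51-bp centered window, leftmost on ties. For summit-centric analyses the
merged peak universe is then refined on the replicate- and factor-pooled
coverage with a read-centroid estimator (`refine_summits()`): for a
symmetric site read distribution the centroid is unbiased with standard
error `spread / sqrt(reads)`, about 1 bp at default depths.

Merging of peak sets is the transitive closure of the >= 1 bp overlap
relation; the merged summit is the summit of the constituent with the
largest signal (leftmost on ties). Differential binding pools counts
over replicates (and both factors when a combined universe is analysed),
computes `fold change = (TAM RPM + 0.5) / (EtOH RPM + 0.5)`, and tests
the pooled TAM count with an exact conditional binomial against the
depth ratio, BH-corrected. This replaces a dispersion-modelling
negative-binomial fit: at simulation depths the Poisson/binomial model
is exact for the generator and keeps the test enumerable by an
independent oracle. Library-size normalisation is total mapped reads
(RPM) throughout.

## Chromatin classification and target mapping

Peaks are classified by their summit with precedence
promoter (H3K4me3) > enhancer (H3K4me1 or H3K27ac) >
repressed (H3K9me3 or H3K27me3) > uncharacterized. The precedence order
is configurable; the summit (not region overlap fraction) is used
because every distance-based analysis here is summit-centric.

Promoter targets: a TSS qualifies if the summit lies within 1500 bp
upstream to 250 bp downstream (strand-aware, inclusive); a summit
downstream of the TSS must additionally lie within 5 percent of the gene
length, which keeps "promoter" assignments from reaching into long gene
bodies. The nearest qualifying TSS wins; ties break to the
lexicographically smaller gene id for determinism. The 5 percent rule is
applied symmetrically by strand. Enhancer targets: any gene whose TSS is
within 50 kb of the summit, or whose body contains the summit
(many-to-many). Genes are partitioned into Pr, Eh and Pr+Eh classes by
which kinds of peaks they carry. Multi-isoform annotations are kept as
separate records (each record contributes its own TSS).

## Pol II metrics

Densities are RPM/kb. The promoter-proximal window is TSS +/- 250 bp;
the gene body is the gene minus its intersection with that window, for
genes longer than 251 bp. The pausing index is promoter density over
body density, reported as missing (never 0 or infinity) when the body
has no signal; genes whose window leaves the chromosome are excluded
with a reason code. Meta-gene profiles use a 1 kb upstream flank and a
2 kb downstream flank in 50-bp bins and 100 equal-fraction gene-body
bins, minus-strand genes reversed; group profiles are per-bin means of
per-gene RPM signal (linear scale, as meta-profiles are conventionally
drawn).

## Super-enhancers

H3K27ac enhancer peaks lacking H3K4me3 are stitched when their gap is at
most 12.5 kb (inclusive, transitive); the stitched signal is the sum of
input-corrected constituent signals, floored at zero. For the cutoff,
ranks and signals are rescaled to [0, 1] and the cutoff is the slope-1
tangent point of the signal-versus-rank curve — the point minimising
`y - x`. For an ideal convex curve this is exactly the point where the
discrete slope crosses 1; unlike a literal "first slope below 1 scanning
from the top" rule it is robust to sampling noise in the top-rank
plateau, which otherwise truncates the called set. Regions strictly
above the cutoff are super-enhancers; an all-equal signal vector yields
none. Gene assignment uses the same 50 kb window measured from the
nearest region edge, or gene-region overlap.

## Motif analysis

PWMs are probability matrices with a pseudocount of 1 per cell applied
at construction; scores are log2 odds against the background, summed
over positions, with ambiguous bases contributing zero bits. Both
strands are scanned (the minus strand via the reverse-complemented
matrix, so a sequence and its reverse complement score identically on
opposite strands). The default hit threshold is 80 percent of the
maximum achievable score — a declared choice, configurable per PWM. Hit
positions are match centers. Density profiles count hit centers per
offset in summit +/- 200 bp, normalised per covered offset. For
stratification, a peak belongs to a motif-combination group if every
motif of the set has a hit center within 50 bp of the summit (inclusive
semantics — additional motifs do not exclude a peak); "Other" is the set
of peaks carrying none of the listed motifs, and each group is compared
with Other by a two-sided Wilcoxon rank-sum test on log2 binding fold
changes. The shipped motif panel is synthetic: consensus-based matrices
named after the motif families relevant to this system (AP-1, CREB, ETS,
KLF/SP1, CEBP), not JASPAR entries; de novo motif discovery is out of
scope and users supply PWMs.

## Expression and cancer-gene enrichment

Ribosome-footprint quantification uses the trimmed ORF: the CDS minus
the first 15 codons after the start and the last 5 codons before the
stop (strand-aware), minus any supplied upstream-ORF mask. RPKM is
`reads x 1e9 / (depth x region bp)`. Genes with fewer than 5 raw reads
in either condition are `filtered` for fold-change purposes — their fold
change is undefined and excluded, never imputed. Differential calls are
twofold, inclusive: up at ratio >= 2, down at <= 0.5. Bound-versus-
unbound comparisons are two-sided Wilcoxon rank-sum tests on log2 RPKM
per condition and on log2 fold change (exact for small untied samples,
normal approximation with tie correction otherwise; fully tied samples
give p = 1). Catalog consolidation takes the union of sources per role;
genes in both the oncogene and tumor-suppressor unions become OncoTSG,
so the final labels are exhaustive and exclusive. Enrichment is a 2x2
Fisher exact test per label over the annotation universe, with the
two-sided p defined as the sum of probabilities of tables no more likely
than the observed one (the `fisher.test` convention, cross-checked
against full hypergeometric enumeration in the tests).

## The synthetic study

The generator is a deterministic function of one seed and defines the
study conditions. Defaults: 3 chromosomes x 2 Mb, 300 non-overlapping
genes (3–12 kb), 2 conditions x 2 factors x 2 replicates, and 400
planted 300-bp binding sites whose class composition
(promoter/enhancer/repressed/uncharacterized = 120/180/24/76) mirrors
the 30/45/6/19 percent split of the modelled factor's sites. Site width
follows the 200–300 bp chromatin fragment range; coverage is read-start
counts (fragment modelling is omitted because every downstream statistic
consumes region counts). Reads are Poisson with a flat background set by
an input depth of 1e6 reads per sample and triangular site kernels whose
expected extra reads are `amplitude x background x width`; amplitudes
are log-normal (median 12-fold) and correlated between the two factors
(target r = 0.9). TAM binding is multiplied by a planted per-site fold
change, log-normal with median 2-fold (binding increases at essentially
all sites on transformation), plus an extra +0.5 log2 at AP-1
motif-bearing sites. Motif consensus strings are planted at summits with
per-motif probabilities (first motif centered exactly at the summit,
further motifs offset by 15–30 bp).

Pol II tracks put `body rate x pausing index` in the TSS +/- 250 bp
window, with log-normal pausing indices (median 4); footprint counts are
Poisson with expectation matching a target RPKM of `2^(log2 baseline)`,
where the baseline is normal (mean 3, sd 1.5 log2), bound genes gain
+1 log2, and genes with both promoter and enhancer input gain a further
+1 log2 — the planted version of the observation that combined
regulatory input drives the strongest transcription. Expression
induction is `0.5 x` the gene's mean planted binding fold change plus
noise. Cancer labels are drawn with probability 0.10 for bound and 0.04
for unbound genes, split ONG/TSG/OncoTSG roughly as in the consolidated
human catalogs. Super-enhancers are planted as 10 clusters of 3 H3K27ac
peaks (1 kb wide, 3 kb gaps) with 8-fold amplitude over background
H3K27ac regions, which are spaced beyond the stitching distance so that
background stitched regions stay simple. DNase background sites follow a
15/25/20/40 class mix, giving promoter/enhancer overrepresentation and
repressed depletion of binding sites relative to accessible chromatin.

What the generator does not emulate: realistic sequence composition and
mappability, GC bias, copy-number artifacts, fragment-length effects,
overdispersion beyond Poisson, and isoform structure. Passing tests
demonstrate internal correctness and statistical calibration of the
pipeline, not performance on real libraries with those artifacts.

## Problem sizes and numerical choices

The default study (3 x 2 Mb) runs the full pipeline in about a minute on
one CPU. Multi-seed property checks (AP-1 stratification, null
calibration) use a proportionally shrunken study — half the genome,
genes and sites at the same densities — so that bound and unbound genes
both occur; null runs plant no sites at all. Degenerate inputs are
contracted explicitly: undefined pausing indices and fold changes are
missing values, fully tied rank tests give p = 1, empty reference groups
and zero-depth inputs are errors, and summit ties always break leftmost
so outputs are deterministic.

## Known limitations

The Poisson read model understates biological replicate variability, so
the differential-binding test is anticonservative on real overdispersed
data (a negative-binomial fit would be the drop-in replacement). The
windowed caller does not model fragment shifts and is not a general
MACS2 substitute; it exists to make the confident-peak filter and
everything downstream of it testable end-to-end. Super-enhancer calling
omits the TSS-exclusion refinement of the original ROSE. Motif analysis
scans user-supplied PWMs only.
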