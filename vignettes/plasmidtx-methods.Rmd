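---
title: "Methods and design of plasmidtx"
author: "plasmidtx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of plasmidtx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameter choices and numerical
conventions behind `plasmidtx`, and what the synthetic-data tests do
and do not establish about real data.

# Scope and data model

The package analyses a single plasmid (or chromosome) contig with
stranded gene annotation. Containers follow Bioconductor conventions:
`GenomeBundle` pairs a `DNAStringSet` with a `GRanges` of genes,
`CoverageTrack` holds one per-base depth `Rle` per strand,
quantification returns a `SummarizedExperiment`, and call tables are
`DataFrame`s. All in-memory coordinates are 1-based inclusive, the
native convention of `IRanges`/`GRanges`; on disk, GFF3 stays 1-based
and bedGraph 0-based half-open, with `rtracklayer` doing the
translation. Keeping the memory model on the Bioconductor convention
rather than a 0-based internal scheme removes one coordinate
translation layer and lets every range operation fall through to
`GenomicRanges`.

# Expression quantification and tiering

RPKM and TPM are computed from gene-level fragment counts:
`rpkm = numReads / ((geneLength/1e3) * (totalNumReads/1e6))` and
`tpm = 1e6 * rate / sum(rate)` with `rate = count/length`. Tier
assignment applies an expression floor (default 1.5 RPKM) and then
quartiles computed *on the expressed genes only*: `silent` below the
floor, `high` above Q3, `low` at or below Q1, `medium` between.
Choices that the tiering rule leaves open:

* **Quantile method.** Linear-interpolation (type-7) quantiles, R's
  default, documented so the thresholds are reproducible elsewhere.
* **Boundary assignment.** `high` is strictly above Q3 and `low`
  closed at Q1, which partitions without overlap; the boundaries only
  matter for ties.
* **Replicates.** One tier per gene, from the mean RPKM across
  samples; per-replicate tiering would create artificial tier
  flipping at quartile boundaries.

Note a structural consequence of quartile tiering: the called tier
proportions are fixed by construction (roughly 25/50/25 among
expressed genes), so on synthetic data they need not equal the
generator's planted tier proportions, and recovery tests compare
planted *parameters* (spacer laws, boundaries, classes), not tier
counts.

# Transcript boundaries from coverage

A TSS is called where the strand's coverage steps up, a TTS where it
steps down, scanning in reading orientation; the minus strand is
handled by reversing the track, which makes the two calls exact
mirror images. A position `i` is a candidate when the median depth
over `[i, i+window)` reaches
`max(minDepth, ratio * median over the upstream flank)`
(defaults: window 5 nt, flank 50 nt, minDepth 10, ratio 3). Runs of
candidates closer than the window are merged; within a run the
reported position is the first base whose own depth clears the
threshold -- the step onset -- which recovers clean steps exactly.
Positions without a full upstream flank are not callable, so edges of
the contig cannot fire spuriously. The windowed median was chosen
over a derivative filter because it is robust to single-base noise
and has only interpretable parameters.

Consecutive same-strand genes join into one transcriptional unit when
the inter-gene coverage never drops below 0.25 of the smaller
flanking-gene mean depth and no TSS intervenes; 0.25 is deliberately
conservative and exposed as `joinRatio`. Units take the nearest
upstream TSS and downstream TTS within 300 nt search limits.

Coverage-derived TSS calls on real RNA-seq tend to under-estimate the
5' UTR by roughly 20 nt, so when a promoter is placed the unit's TSS
is re-anchored to 7 nt downstream of the -10 hexamer's 3' end --
within the 6-8 nt prokaryotic norm, fixed at 7 for determinism --
and the UTRs recomputed. Refinement never moves a TSS to or beyond
the first start codon; such cases keep the coverage TSS and are
flagged.

# The promoter model

The promoter is modelled as two hexamer position-weight matrices
(-35 and -10) and a prior over spacer lengths 15-19 nt, seeded from
the canonical consensus TTGACA/TATAAT (initial consensus-base
probability 0.7) with a uniform spacer prior. Fitting is a
two-block, hard-assignment EM over upstream windows (62 bp by
default): the E step takes each sequence's best placement under
summed log2 odds against the window base composition plus the log
spacer prior (ties to the most upstream placement, then the shorter
spacer); the M step rebuilds both PWMs with pseudocount 0.5 per cell
and the spacer prior with pseudocount 0.5 per class. Iteration stops
when no PWM entry moves more than 1e-4, or at 100 iterations with a
warning. The fit is deterministic and anchored -- this is consensus
refinement, not de-novo motif discovery, which matches how the
canonical bifidobacterial promoter is actually used in practice.

Scanning reports the best placement when its score reaches 4 bits
(configurable); the `pos10 + 5` coordinate of a call maps back to the
genomic 3' end of the -10, which is what boundary refinement
consumes. Per-column information content of aligned sequences is
`2 + sum(f * log2 f)` without small-sample correction. One caveat
found while characterising the fit: because the E step aligns each
window at its best-scoring position, even random sequences yield
apparent information around 0.5 bits; the `informative` flag (mean
column IC below 0.5 bits) therefore separates random from planted
input reliably only from roughly 30 sequences upward, and fits on
fewer windows should be inspected rather than trusted to the flag.

# Regulon motif scanning

The 34 bp degenerate consensus
`AWAYATGYTATACTGAATATGTCCACATAAAAWA` (positions 9-14 are the -10
hexamer) is scanned over the 60 bp upstream of every annotated start
codon, on the gene strand, with an explicit mismatch budget and IUPAC
semantics (W = A/T, Y = C/T, N = any). The matching primitive is
`Biostrings::matchPattern(fixed = "subject")`, with placements
overhanging the window discarded; the test suite checks the scanner
against an independent position-by-position comparison. At zero
mismatches on a 20 kb synthetic genome the scanner returns exactly
the planted instances.

# Terminators

Hairpins are perfect Watson-Crick inverted repeats (no G:U, no
bulges in this version -- an extension point), stems 5-15 nt and
loops 3-10 nt, scored 3 per G:C pair and 2 per A:T pair; overlapping
candidates are pruned greedily to the best score. Classification
searches 20 nt before to 150 nt after the TTS and applies a strict
precedence: hairpin with stem GC fraction >= 0.5 and at least 4 T in
the 8 nt after the stem = rho-independent; hairpin without the
poly-T = stem-loop; otherwise an opposite-strand unit with a 3' end
within 100 nt (or overlap) = convergent; else none. Every unit gets
exactly one class.

Because short perfect inverted repeats are abundant by chance in
GC-rich sequence (in 60% GC background, a stem-5 repeat is expected
roughly once per 130 nt of search region), only hairpins scoring at
least 20 -- e.g. a 7 bp all-GC stem -- count as terminator
candidates. Without this floor, chance hairpins systematically mask
the convergent class.

# Codon usage

`RSCU = count / (family total / family size)` per synonymous family;
stop codons and the single-codon families (Met, Trp) are excluded
from RSCU, CAI and CBI throughout. CAI follows the Sharp-Li
convention: relative adaptiveness `w = RSCU / max(RSCU in family)`
on pooled reference counts, reference-absent codons floored at 0.01,
and the gene score is the geometric mean of `w` over its
family-codons. CBI follows Bennetzen-Hall:
`(N_opt - N_rand) / (N_tot - N_rand)` with `N_rand` the expected
optimal-codon count under uniform family usage. GC3 is computed over
all sense codons (not synonymous-only GC3s), matching the plain
definition of wobble-position composition; `gc3 = c3 + g3` exactly.
Hydropathy is the mean Kyte-Doolittle index, aromaticity the F/Y/W
fraction.

Anticodon decoding is strict reverse complement (wobble rules are
deliberately out of this version: they would add codons a tRNA *may*
read, which changes compatibility summaries in ways that deserve
their own validation). Rare codons are those under 10% within-family
usage. Profile comparison runs Pearson's chi-squared on the raw 2 x k
count table -- not on RSCU values, which are ratios and violate count
assumptions -- pooling codons with expected counts below 1 into one
column, without continuity correction.

# Carriage differential expression

The procedure mirrors the plasmid-carriage comparison design: a TPM
matrix, two-way structure explored by k-means on per-gene z-scores of
`log2(TPM+1)` with the number of clusters chosen at the SSE elbow
(maximal second difference, ties to the smaller k, 10 seeded
restarts), and per-gene calls filtered at fold change >= 2 (read as
|log2fc| >= 1), p < 0.05 and Benjamini-Hochberg FDR < 0.1, after a
mean-expression pre-filter (1 TPM).

Two numerical points matter with three replicates per condition:

* **Composition bias.** TPM sums to a constant per sample, so an
  asymmetric effect (127 genes up versus 30 down) deflates every
  null gene's TPM in the affected condition by a shared factor. Fold
  changes are therefore computed on TPM columns rescaled by
  median-of-ratios size factors (condition means floored at 0.5 TPM
  to avoid division by zero); without this, null genes acquire a
  systematic negative log2fc and the false-discovery rate is not
  controlled.
* **Variance moderation.** An unmoderated per-gene Welch test on
  n = 3 has 4 degrees of freedom; its heavy tails leave true effects
  with q-values far above 0.1 and the procedure essentially
  powerless. Per-gene p-values therefore come from the standard
  small-n RNA-seq machinery: TMM normalisation and precision-weighted
  moderated t-statistics (limma-voom), i.e. empirical-Bayes pooling
  of variance information across genes. The simple two-group Welch
  test (with a 1e-3 variance floor so identical groups give p = 1)
  remains available as `geneTest()` for effect-size estimation and
  small fixtures.

Enrichment is functional-class scoring: a Wilcoxon rank test of a
gene set's log2 fold changes against the complement, exact by
enumeration for sets of at most 8 in backgrounds of at most 25
without ties, otherwise the normal approximation with tie
correction.

# The synthetic-data generator

The generator is the package's test bed: it emulates the features the
analyses target, with every planted parameter recorded in a
`TruthSet`.

* **Background**: i.i.d. bases at 60% GC over 20 kb -- the high-GC
  regime of bifidobacterial replicons; 20 genes by default in
  proportions 30/30/20/20% high/medium/low/silent.
* **Promoters**: -35/spacer/-10 upstream of each non-silent gene,
  with the TSS 7 nt downstream of the -10. Mismatch budgets to the
  consensus are 1/2/3 for high/medium/low tiers; spacer laws put the
  mode at 17 nt for high-tier and 16 nt for medium-tier promoters,
  the contrast the spacer statistics are meant to recover. 5' UTRs
  are drawn 28-38 nt for high-tier and 20-32 nt otherwise (so
  highly expressed units have longer mean 5' UTRs), 3' UTRs
  15-40 nt.
* **Terminators**: 50% rho-independent (8 bp all-GC stem, 4 nt loop,
  7 nt poly-T), 20% bare stem-loops (non-T tail), 30% convergent --
  planted as adjacent opposite-strand gene pairs whose 3' ends lie
  about 28 nt apart, with no hairpin.
* **Regulon motifs**: six instances of the 34 bp consensus with W/Y
  resolved randomly, each overlapping the -10 of a distinct
  high-tier gene (which therefore carries the motif's TATACT -10,
  one mismatch from consensus).
* **Coverage**: fragments (30 nt by default) placed uniformly over
  each transcript and clipped at its boundaries, at tier depths
  200/100/50x by default, over a Poisson(0.2) per-base background.
  Clipping makes coverage uniform across the whole transcript with
  sharp steps at both ends -- the profile boundary mapping reads --
  rather than leaving fragment-length ramps that would bias every
  boundary call by a systematic offset; clipped bases are logged so
  coverage mass remains accountable. A practical noise ceiling of 6x
  (the Poisson(0.2) background essentially never exceeds it over a
  gene body) is what "quiet" means for silent genes.
* **Counts**: 1864 genes, two conditions, three replicates,
  log-normal baselines (meanlog log 50, sdlog 1 -- right-skewed, as
  real count tables are), negative-binomial dispersion 0.1, with
  127 up- and 30 down-regulated genes planted at |log2fc| = 2.

What passing these tests shows -- and does not. Recovery on this
generator demonstrates internal correctness: the algorithms find what
the model plants, at the planted signal strengths. Real data differ
in ways the generator deliberately omits: coverage is not uniform
within transcripts (fragment bias, rRNA residue), promoters vary in
architecture beyond mismatch counts, terminator hairpins have bulges
and G:U pairs, codon usage is shaped by amino-acid composition, and
count dispersion varies per gene. Results on real data therefore
inherit the algorithms' assumptions, not the recovery rates.

# Determinism, problem sizes and error handling

Every simulator routes its `seed` through an internal scope that
restores the caller's RNG state, so outputs are pure functions of
(parameters, seed) and repeated runs are byte-identical, which the
test suite checks down to the on-disk files. The bundled problem
sizes -- 20 kb genomes, 20 genes, 1864-gene count designs, three
replicate simulations for expectation-type checks -- were chosen so
the full suite and the demo pipeline run in minutes on one core while
keeping every statistical check comfortably powered. Degenerate
inputs fail loudly and early: all-zero samples, fewer than four
expressed genes, fewer than ten promoter windows, frame or
internal-stop violations in CDSs, invalid IUPAC codes and impossible
generator requests all raise errors naming the offending quantity.

# Interface note

The package is used from R: the exported functions, `runPipeline()`
for the end-to-end demo, and `scripts/acceptance.R` for the worked
values are the entry points. No shell CLI is shipped; the pipeline
function writes the same standard formats (FASTA, GFF3, bedGraph,
TSV, JSON) a command-line tool would.
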