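---
title: "circkit methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

`circkit` implements the analysis stages that follow circRNA detection in a
two-group RNA-seq study: confidence filtering of back-splice junction (BSJ)
calls, RPM quantification and differential abundance, structural
classification, genomic features of circRNA-producing loci, and
splicing-factor motif profiling. This vignette documents the statistical
models, every tunable parameter that matters, the synthetic data the test
suite runs on, and the design decisions that were genuinely open.

## Coordinates and inputs

All internal coordinates are 1-based inclusive, matching CIRI2 tables and
GTF; BED (0-based half-open) is converted on read, and converting
BED → internal → BED is the identity. Chromosome names are matched exactly
across inputs — no `chr` prefix normalization is attempted, since silent
renaming causes harder bugs than a loud mismatch. Duplicate call rows for
one junction within a sample are merged by summing reads, with a warning.

## Tier filtering

The three confidence tiers are independent per-circRNA predicates over the
junction-count matrix:

* **Tier 1**: maximum count over samples ≥ 2.
* **Tier 2** (default, sum rule): present (count ≥ 1) in ≥ 2 samples *and*
  total count ≥ 5. An alternative per-sample rule (≥ 5 reads in each of
  ≥ 2 samples) is selectable with `tier2_rule = "per_sample"`; the two
  rules circulate side by side in the literature and differ for shallow,
  widespread junctions, so both are implemented and the choice is explicit.
* **Tier 3**: present in all or all-but-one samples, *regardless of read
  number*.

Because tier 3 ignores depth, a junction seen once in every sample is
tier 3 but not tier 1 — the tiers deliberately do not nest, and no nesting
is imposed; callers combine predicates as needed. "Present" means
count ≥ `presence_threshold` (default 1).

## Quantification and differential abundance

RPM is `count × 10⁶ / mappable_reads` per cell, applied identically to
junction and non-junction (linear) counts. The fold change is computed on
group-mean RPM with a pseudocount:
`log2FC = log2((mean_case + ε)/(mean_control + ε))`, ε = 0.01 RPM. The
pseudocount keeps circRNAs absent from one group finite without dominating
typical RPM magnitudes (most junction RPMs in a 2 M-read library with tens
of supporting reads are in the 1–100 range, so 0.01 is two orders below).

The test is a two-tailed two-sample t-test on per-sample RPM values.
**Welch** (unequal variances) is the default — it is the default of the
common statistical environments and degrades gracefully when group
variances differ; the pooled-variance Student variant is available via
`var_equal = TRUE` for compatibility with classical usage. The test runs on
untransformed RPM by default, with `log_transform = TRUE` switching to
`log2(rpm + ε)`. Raw p-values are reported by default (direction calls
combine p < 0.05 with a fold-change threshold of |log2FC| ≥ 1, which
already controls the practically irrelevant hits); Benjamini–Hochberg is
available via `p_adjust = "BH"`. Degenerate inputs are defined, not
errors: two constant equal groups give p = 1 and log2FC = 0; constant
unequal groups give p → 0.

Direction summaries use Pearson's chi-squared without continuity
correction (against a 50:50 split for one collection, on the 2×2
collection-by-direction table for two). The circular–linear relationship
is the squared Pearson correlation of paired mean RPM vectors; constant
input yields a missing value rather than an error.

## Structural classification

Each BSJ end is assigned a context against the host gene with the
precedence *exon boundary* > *inside exon* > *inside intron* >
*outside gene*; boundary matching is exact (±0 nt) by default because
CIRI2 coordinates are splice-site resolved, with `boundary_slop`
accommodating off-by-one dialects. The category is a deterministic
function of the two contexts: both exonish → `exonic`; both inside one
intron → `intronic`; mixed combinations → the corresponding mixed class;
both outside → `intergenic`. Two ends in *different* introns necessarily
span exons, so that combination is classified `exonic+intronic` — the
rules only name the both-in-one-intron case, and this is the reading
consistent with the molecule's actual content. The host gene is the one
named in the record; records without one are classified against the
(alphabetically first) overlapping gene and flagged ambiguous when several
overlap. Strand mismatches between record and gene are flagged but do not
change the classification, since both strands produce circRNAs from the
same loci.

Length is the genomic span (`end − start + 1`): internal structure is not
observable from short-read BSJ calls, so spliced length is reported only
when exon chains are supplied. Length classes use edges {200, 1000, 5000},
each class including its lower edge; the named 200–1000 nt class is the
conventional one, and the outer edges were fixed once as round numbers
bracketing the observed range of circRNA spans.

Isoform groups: `same_bsj` groups need explicit exon-chain labels (the
package takes no position on where that evidence comes from — an optional
input table is the stand-in for assembler output); `shared_donor` /
`shared_acceptor` groups are formed within a gene over distinct BSJs
sharing exactly one end, with donor/acceptor resolved by strand (on `+`
the BSJ start is the acceptor side).

## Locus features

**Flanking introns.** The host transcript is the longest (genomic span)
transcript containing both BSJ ends, falling back to the longest
overlapping one; ties break to the smallest transcript id so the choice is
deterministic. Upstream/downstream are transcript-orientation notions;
terminal-exon circRNAs get a missing value on the absent side. Group
comparisons (up vs other, down vs other) use the pooled-variance Student
t-test with a zero-variance guard (equal constant groups → p = 1; distinct
constant groups → ε-inflated variance, p ≈ 0), and the "other" control
pool can be subsampled without replacement under a fixed seed.

**RCM detection.** For every (upstream repeat, downstream repeat) pair
annotated in the two flanking introns, the upstream sequence is aligned
locally (Smith–Waterman) against the reverse complement of the downstream
sequence with match +1, mismatch −1, gap −2 (linear). Pairs with
alignment length ≥ 20 nt and identity ≥ 80 % are reported. The scoring and
thresholds emulate a megablast-style screen at desk scale and are fully
configurable; identity is computed over the alignment including gaps.
Co-oriented copies do not align against the reverse complement and
correctly produce nothing. Duplex free energies are out of scope; the
output table leaves room for an external ΔG column.

**Splice-site strength.** Windows follow the canonical maximum-entropy
convention: 9 nt for the donor (3 exonic + 6 intronic) and 23 nt for the
acceptor (20 intronic + 3 exonic), in transcript orientation. Scoring is
pluggable. The default scorer is a first-order-free PWM estimated from
every annotated internal splice site of the supplied GTF with pseudocount
1, scored as log2 odds against the genome's base composition — it needs no
external model files and gives 0 for a window drawn from background, so
scores are comparable within a run. A published model can be supplied as
exact sequence → score lookup tables (`load_splice_model()`); scores from
different models are not comparable across runs. At a BSJ the scored
windows are those of the back-splice's own would-be intron (donor at the
circRNA 3′ end, acceptor at the 5′ end); annotated-site scores for the
same gene are available separately, so both readings of "splice-site
strength at the BSJ" can be computed and labeled. Windows running past a
contig end or containing N yield missing scores with a flag.

**Cryptic sites and dinucleotides.** A BSJ end is `annotated` when it
exactly matches the appropriate exon boundary (exon start for the circRNA
start, exon end for the end), `ie_bsj` inside an exon, `ii_bsj` inside an
intron (with the containing intron's transcript-orientation ordinal), or
`outside`. "Annotated" is defined relative to the supplied GTF — an
annotation-relative definition replaces any external splice-site
prediction service, keeping the classification reproducible. The
dinucleotides immediately outside the BSJ (first two intronic bases after
the donor, last two before the acceptor, transcript strand) are reported
in DNA alphabet, with GT/AG flagged canonical (GU/AG in RNA).
Ends outside genes still get dinucleotides; only the intron index is
meaningless there. The 3′-UTR flag requires CDS features in the GTF and is
missing otherwise.

## Motif profiling

MBNL1's default set is all YGCY 4-mers plus the literal 5-mers UGCUU and
GCUGC. GCUGC does not itself match YGCY; it is included because the
published motif inventories list it alongside the YGCY class, and the set
is fully user-overridable. CUGBP1's default is overlapping UGUG
occurrences, with a run-based alternative (maximal (UG)n, n ≥ 3) for
analyses that prefer counting contiguous UG tracts once. Counting is
overlapping in all modes — the common CLIP-motif convention and the more
sensitive choice; U and T are equivalent and N never matches. Profiled
regions are the circularized exon body and windows of 250 nt (default)
into each flanking intron, in transcript orientation, truncated (and
flagged) at short introns.

Single-exon circRNAs (BSJ exactly matching one annotated exon) are
compared with a supplied cassette-exon table on exon length, flanking
intron lengths and splice-site scores, feature-wise with pooled Student
t-tests and pairwise exclusion of missing values, plus the count of exons
shared exactly between the two sets.

## The synthetic data generator

The generator emulates the *structure* of a two-group circRNA study, not
any particular organism: ~40 genes of 4–8 exons (80–400 nt) on one
chromosome, introns of 0.2–2 kb except circRNA-flanking introns drawn from
2–20 kb (so the flanking-intron contrast has known truth), canonical GT/AG
written at every intron's transcribed ends, one transcript per gene with a
second exon-skipping transcript on some non-circRNA genes. Half of the
genes host planted circRNAs cycling through the structural classes
(multi-exon and single-exon exonic at annotated boundaries, intronic
inside first/second introns, exonic+intronic, inside-exon `ie` ends
including terminal-exon cases, and a small intergenic fraction in the
spacers, default 0.5 %, to exercise the exclusion rule); 20 % of circRNA
genes host three BSJ variants sharing ends, giving MCG and isoform-group
truth.

Junction counts are negative binomial with mean
`base_mean × 2^(log2FC·case) × library_size_s / nominal` and variance
`μ + φμ²` (φ = 0.1 by default, the typical bulk RNA-seq scale; φ = 0 gives
Poisson). Per-circRNA base means are log-normal around 50 junction reads —
well-supported junctions, appropriate for a generator whose plantings
should be recoverable rather than marginal. Half of the planted circRNAs
are differential (`frac_differential = 0.5`, a field added because a
direction summary needs a defined differential fraction), at |log2FC| = 2
with 90 % planted up, mirroring the strongly asymmetric direction balances
reported in disease tissues. Linear (non-junction) counts are drawn
independently, so the circular–linear correlation is ~0 by construction.
Library sizes wobble uniformly ±10 % around 2 M mappable reads.

Repeat pairs (30 nt, default 100 % identity) are planted at the midpoints
of the two flanking introns of 60 % of eligible circRNA loci as exact
reverse complements, plus co-oriented copies at a further 20 % as negative
controls; multi-circRNA genes are excluded because their variants share
flanking introns and plantings would overwrite each other. Motif plantings
default to 5 copies of UGCUU in the downstream 250-nt window for 50 % of
single-circRNA exonic loci — enough that the planted enrichment clearly
exceeds the background YGCY rate of random sequence (a YGCY match occurs
at ~4/256 of positions by chance, ~4 expected hits per 250-nt window).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: realistic splice-site motif structure beyond
the GT/AG dinucleotides (the PWM scorer's absolute values on synthetic
data are not biological), repeat family structure (planted repeats are
random sequence, not Alu consensus), GC/composition biases, overlapping
genes, sequencing error, or detector false positives. The generator
validates the *bookkeeping and statistics* of the pipeline, not biological
discovery.

Determinism: every draw flows from the single integer seed through R's
default generator, restoring the caller's RNG state afterwards; two runs
with one seed produce byte-identical FASTA/GTF/BED/TSV outputs.

## Problem sizes and runtime

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite stays interactive: the default simulated study is 40 genes
(~1 Mb genome, ~30 circRNAs, 8 + 8 samples); the count-model checks use
2,000 null circRNAs and 1,200 fold-change circRNAs at 8 + 8; the
brute-force cross-checks use 200 random count matrices (≤ 10 × ≤ 50) and
1,000 random sequences (≤ 500 nt). The end-to-end pipeline on the default
study completes in well under a minute on one CPU.

## Known limitations

* No read alignment, junction detection, or BAM parsing — the CIRI2 table
  is the entry point, and detector artifacts propagate.
* Internal circRNA structure is taken on faith from optional exon-chain
  input; genomic span systematically overstates spliced length for
  multi-exon circRNAs.
* The default PWM splice scorer is first-order-free; it cannot capture the
  positional dependencies a maximum-entropy model encodes. Supply a
  lookup-table model when calibrated scores matter.
* Motif counts are sequence statistics; no claim of in vivo binding.
* The t-test operates on per-sample RPM without count-model shrinkage;
  with few samples and very low counts a dedicated count model has more
  power. The tier filters exist precisely to keep such junctions out of
  the tested set.
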