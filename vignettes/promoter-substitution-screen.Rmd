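---
title: "Screening for promoter substitutions from segmented copy-number profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for promoter substitutions from segmented copy-number profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promsub)
```

## The problem

A promoter substitution (PS) places the body of one gene under the control of
another gene's promoter. The textbook example is *TMPRSS2*–*ERG* in prostate
cancer, where an interstitial deletion fuses the strongly expressed *TMPRSS2*
promoter to the *ERG* body. Whole-genome sequencing detects such
rearrangements directly but is available for comparatively few tumors.
SNP-array copy-number profiles are abundant, and intrachromosomal deletions
and tandem duplications leave unambiguous footprints in them: a deletion
removes one copy of an interval, a tandem duplication adds one. `promsub`
exploits this to call candidate PS events from segmented copy-number (SEG)
data at cohort scale and to test whether the putative 3' partner is
transcriptionally induced when it gains a stronger promoter.

The trade-off is inherent to the data type: arrays say nothing about
inversions or interchromosomal events, breakpoint resolution is limited to
the probe grid, and amplitude is diluted by normal-cell admixture. The
pipeline compensates with strict filters rather than with purity/ploidy
modelling, which is also why every threshold below is exposed in a single
configuration object (`ps_config()`).

## From segment means to structural variants

Each SEG record carries a log2 tumor/normal ratio (`seg_mean`). Segments are
assigned one of five states by fixed cut points, each bin closed on the left
and open on the right:

| state   | interval           | interpretation       |
|---------|--------------------|----------------------|
| HOMDEL  | x < −1             | homozygous deletion  |
| HEMIDEL | −1 ≤ x < −0.2      | hemizygous deletion  |
| NEUTRAL | −0.2 ≤ x < 0.3     | copy-neutral         |
| GAIN    | 0.3 ≤ x < 0.7      | single-copy gain     |
| AMP     | x ≥ 0.7            | amplification        |

Consecutive same-state segments closer than `merge_gap_max` (100 kb) are
merged, with the merged amplitude taken as the probe-count-weighted mean —
this preserves the array-level evidence, although the amplitude is not
re-used after classification, so the weighting choice is inert downstream.
Segments flanking a no-data gap larger than `nodata_gap_min` (100 kb) are
dropped as unreliable; a gap of exactly the threshold is tolerated, and
chromosome ends do not count as gaps.

Three rules then turn state runs into SV calls:

* a HEMIDEL segment with no HOMDEL neighbour is a deletion (**DEL**);
* a HOMDEL segment flanked on both sides by HEMIDEL segments is a deletion
  (the nested loss inside a one-copy region);
* a GAIN segment with no AMP neighbour is a tandem duplication (**TDUP**).

A chromosome-terminal segment has no neighbour on one side; an absent
neighbour satisfies "not HOMDEL"/"not AMP" (there is no disqualifying state)
but cannot satisfy "is HEMIDEL". Event breakpoints are the first and last
base of the event segment — the true break lies somewhere in the flanking
probe gap, so downstream gene matching treats breakpoints as points with no
extra slack. Calls smaller than `sv_min_size` (15 kb) or with a breakpoint
within `telocent_excl` (2 Mb) of a telomere or centromere boundary are
removed; both comparisons are inclusive ("within 2 Mb" removes a breakpoint
at exactly 2 Mb).

## From breakpoints to promoter substitutions

Breakpoints are annotated against a GENCODE-style gene model with a strict
priority: an overlapping coding gene, else an overlapping lincRNA, else the
closest upstream gene. "Upstream" is strand-aware — the position must lie 5'
of the candidate's TSS along the candidate's own reading direction — and the
distance runs from the position to the TSS. Among several overlapping coding
genes the smallest span wins (the most specific locus), with a final
lexicographic tie-break on `gene_id` for determinism. Overlap uses the full
gene body, not exons: the array data cannot resolve exon-level junctions, so
nothing finer is claimed.

The junction geometry decides the roles. A deletion joins
`…(left of bp1) | (right of bp2)…`; a tandem duplication joins
`…(up to bp2) | (from bp1)…`. On the plus strand transcription flows
left-to-right across the junction, so the promoter donor is the gene at
`bp1` for a deletion and at `bp2` for a duplication; on the minus strand the
sides swap. Two geometries count as PS:

* **FUSION** — both breakpoints inside coding genes transcribed in the same
  direction; the donor's TSS-containing portion survives on the junction's
  5' side, the other gene is the activated 3' partner.
* **UPSTREAM** — exactly one breakpoint inside a coding gene with its 5'
  part (including the TSS) retained at the junction, the other breakpoint
  intergenic and annotated upstream of a same-strand coding gene within
  `upstream_window` (200 kb): readthrough from the donated promoter can then
  drive the downstream gene.

An SV internal to one gene, an opposite-strand pair, or an upstream
annotation pointing back at the donor itself is not a substitution. Only
coding genes may be partners, on both sides; a lincRNA can win the
annotation priority at a breakpoint, but such an event is discarded rather
than re-annotated — the annotation records what sits at the junction, and a
junction inside a lincRNA is not a coding-gene fusion. Both role-assignment
tables are validated exhaustively in the test suite against an independent
junction-construction oracle that enumerates every SV type × strand ×
breakpoint placement on a two-gene toy chromosome (360 cases).

## The expression screen

Expression enters as a linear gene × sample matrix; every statistic works on
`log2(x + 1)`. The pseudocount is the standard choice for RNA-seq-derived
values and makes a zero baseline well defined.

For a gene pair in a cancer type, with affected samples those carrying the
pair's PS event:

* **promoter strength difference** = `log2(median5' + 1) − log2(median3' + 1)`,
  medians over *unaffected* samples of that cancer type only, so a recurrent
  event cannot inflate its own baseline;
* **induction** = per affected sample, `log2(x + 1) − log2(median_unaff + 1)`.

The global strength–induction association dichotomizes each event at 0 on
both axes (cut points configurable; nothing in the method fixes them
elsewhere) and applies a two-sided Fisher's exact test to the 2×2 table.

The recurrence screen takes every (pair, cancer type) with at least
`recurrence_min` (2) distinct affected samples and a donor promoter at least
`stronger_promoter_fold` (2)-fold stronger, tests the 3' partner's
expression with a two-sided pooled-variance Student's t-test (Welch is
available behind `welch = TRUE`), and controls the FDR with
Benjamini–Hochberg across exactly the screened candidate set — not across
all conceivable pairs, since the candidate set is what the screen asserts
anything about. Candidates whose test is undefined (fewer than two usable
affected samples, or zero variance in both groups) are kept with p = 1 and a
flag rather than silently dropped, so the BH denominator is honest.
"Unaffected" means not carrying *this* pair's event; samples with other
alterations of the same genes are not excluded, which biases the screen
conservatively if anything.

Per-case comparisons (altered tumors vs the rest) use the Wilcoxon rank-sum
test: exact when both groups have at most 10 samples and no ties, otherwise
the normal approximation with tie and continuity correction.

## Concordance with WGS calls

A CNA-inferred SV corresponds to a WGS SV of the same sample and chromosome
when both breakpoints agree within `wgs_match_tol` (100 kb, the scale of
array probe resolution). Assignment is greedy one-to-one by smallest total
offset, ties broken by WGS input order; a reciprocal-overlap strategy
(`match_strategy = "overlap"`) is available since no external convention
fixes the criterion. The summary reports the matched fraction and, among
matches, the fraction with coherent DEL/TDUP classification.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the full input stack — genome reference, gene
model, SEG profiles, expression, labels — plus a truth ledger, so every
stage is testable at desk scale. The DNA layer plants non-overlapping
deletions (copy number 2 → 1, optionally with a nested 0 core) and tandem
duplications (2 → 3) on a diploid background, well clear of the
telomere/centromere exclusion zones. The observed segment mean follows the
mixture model

```
seg_mean = log2((purity · CN + (1 − purity) · 2) / 2) + N(0, σ)
```

floored at −8 (the array's effective dynamic range; a homozygous loss in a
pure tumor would otherwise be −∞). Segment boundaries are jittered uniformly
within ± one probe spacing (default 3 kb, the SNP-array scale) to stand in
for probe-grid discretization, and recovery tests match breakpoints at that
tolerance. Ploidy is fixed at 2: the purity mixture alone is enough to
exercise the threshold behavior the pipeline depends on, and ploidy
estimation is explicitly out of the method's scope.

Defaults describe the study conditions: 2 cancer types × 25 samples, 3
chromosomes of 60 Mb, 6 background SVs per sample of 50 kb–2 Mb, amplitude
noise σ = 0.05, purity 0.7 — a typical tumor-cell fraction for TCGA
material, and the regime the classification thresholds are designed for
(at purity 0.7 a one-copy loss sits at −0.62, mid-bin). Planted PS pairs are
deletions bridging two adjacent same-strand coding genes; affected samples
have the 3' partner multiplied by the planted fold (default 8), and the
donor's baseline is set `max(2, fold)`-fold above the 3' partner so the
planted mechanism is coherent with the screen's stronger-promoter gate.
`null_cohort()` reuses the identical DNA layer with all folds at 1, which is
what the FDR-control checks run on.

One numerical regime deserves a caveat. At purity exactly 1.0 a hemizygous
deletion's amplitude is log2(1/2) = −1 — precisely the HOMDEL/HEMIDEL
boundary. Noise-free, the left-closed bin classifies it HEMIDEL; under any
symmetric amplitude noise, half of such segments fall below −1, get called
HOMDEL with neutral flanks, and match no SV rule. Deletion sensitivity in a
perfectly pure, noisy cohort is therefore ~50% by construction, and overall
recall ~0.72–0.76 — a property of the fixed thresholds interacting with the
mixture model, not of the caller, and one reason the thresholds should be
read as tuned for realistically impure samples. The test suite documents
this regime as-is; recovery at purity ≤ 0.8 is essentially complete
(recall and precision ≥ 0.99 in the shipped checks).

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10,000 random amplitudes
for the state-classification oracle; 1,000 random state sequences (length ≤
20) for the SV-rule oracle; the exhaustive 360-case geometry sweep; one
50-sample cohort per recovery condition; 200 replicates each for screen
detection (8-fold induction, 3–5 affected vs 100 unaffected, σ = 0.5) and
for null FDR control (≥ 50 candidates per null screen). These sizes give
binomial standard errors well under the margins being asserted while keeping
a full run in minutes.

Other conventions, stated once: coordinates are 1-based inclusive throughout
(the common SEG dialect), and SV size is `bp2 − bp1 + 1`; chromosome names
are normalized by stripping `chr`, with X and Y treated like autosomes
(segment means are already ratios to matched normal); rows with non-finite
`seg_mean` are dropped with a reported count, because real level-3 files
contain them; merging is applied before gap filtering, following the order
in which the operations are defined; and the same-state merge is transitive
in a single pass, so re-merging is a no-op.

## Limitations

Beyond the data-type limits above: the screen's power is weak when affected
samples are few (n = 2–3), which is intrinsic to recurrence screening, not
to the implementation; fusion calls are DNA-side predictions — confirming a
fusion transcript, its reading frame or retained protein domains requires
RNA-seq and is out of scope; and the synthetic cohorts do not model probe
intensities, replication-timing waves, subclonality, or correlated
expression programs, so passing recovery tests demonstrates correctness of
the inference rules under the stated noise model, not performance on any
particular real cohort.
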