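---
title: "Methods: detecting tissue-specific A-to-I RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting tissue-specific A-to-I RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tisedit)
```

## The model

A-to-I editing converts adenosine to inosine in RNA; inosine base-pairs
like guanosine, so an edited transcript reads G at a position where the
genome (and the unedited transcript) reads A. Given a catalog of known
editing sites, every expressed sequence (EST or mRNA read) overlapping a
site is a Bernoulli observation of that site's editing status in the
tissue its cDNA library came from. The screen treats the per-tissue
editing level as the parameter of interest and asks, for each
(site, tissue) pair, whether the editing level in that tissue differs
from the level in all remaining tissues pooled together.

The test conditions on the margins of the 2x2 table

|            | edited | unedited |
|------------|--------|----------|
| tissue T   | a      | b        |
| other tissues pooled | c | d  |

and computes Fisher's exact p-value from the hypergeometric distribution
of `a`. The assumptions are the usual ones for this design: sequences are
independent draws within and across tissues, each sequence reports the
site's status without allele-specific bias, and the pooled column is an
exchangeable background for the tissue column. Within each tissue, the
family of all testable sites is corrected with the Benjamini-Hochberg
step-up rule: with the m p-values ranked ascending, the procedure rejects
ranks 1..k where k is the largest i with p(i) <= (i/m) q. Reported values
are BH adjusted p-values (the min-over-larger-ranks form), so rejection
is exactly `adjusted_p <= q`.

## Tunable parameters

* `fdr_q` (default 0.05): the FDR level applied within each tissue.
* `sidedness` (default two-sided): the two-sided p-value sums all
  hypergeometric outcomes whose probability does not exceed that of the
  observed table; the `greater` option sums the tail with edited count in
  the tissue at least `a`. Two-sided is the neutral default for "is the
  editing level different"; the one-sided option encodes the enrichment
  reading, "is this site *more* edited in this tissue", which is what
  "tissue-specific editing" usually means in practice. The recovery
  simulations below use the one-sided option for exactly that reason: a
  strong enrichment in one tissue makes the *depletion* of every other
  tissue relative to its (now inflated) pool genuinely significant
  two-sided, so a two-sided screen intentionally reports those mirror
  pairs as well.
* `min_edited_in_tissue` (default 1): a site is only testable in a tissue
  where at least this many edited sequences were observed. The default
  prevents a (site, tissue) pair from being called on pool-side signal
  alone while keeping every observable candidate in the family.
* Library curation: annotations are trimmed and case-folded; empty
  annotations are excluded as "no tissue source", annotations containing
  a configurable substring (default `mix`, `pool`) as "mixed tissue
  sample". An optional merge map collapses synonyms and normal/cancer
  qualifiers (e.g. "brain tumor" into "brain") into one category.

## Counting rules

Bases are recorded on the genome plus strand and complemented onto the
transcript strand once, in the classifier — never in the readers — so no
double-complement can occur. Transcript-strand G counts as edited and A
as unedited; C, T and N (a SNP or sequencing error at the site) are
excluded from both counts rather than counted as unedited, since counting
them as unedited would bias editing levels downward. A sequence
contributes at most one observation per site (duplicates by sequence id
are dropped, first kept), and observations from excluded libraries are
dropped. All dropped and omitted counts are reported, and the retained
plus omitted observations always partition the input.

Coordinates are 1-based and fully closed everywhere inside the package;
0-based half-open BED input is converted at the reading boundary. The
site catalog is authoritative for strand: observation rows that disagree
are dropped and counted rather than silently re-stranded.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure of the real
inputs: a site catalog with random coordinates and strands, per-tissue
library sets plus optional decoy libraries annotated `mixed` or empty
(to exercise both exclusion rules), and per-(site, library) observation
counts drawn binomially at a background editing level, elevated to the
configured effect level for planted (site, tissue) pairs. Bases are
emitted as plus-strand letters honoring each site's strand, so the
strand-aware classifier path is always exercised. A single integer seed
drives one generator stream, and identical configurations with identical
seeds reproduce datasets byte for byte.

What the generator deliberately does not emulate: alignment artifacts,
sequencing error, SNP contamination at editing sites, and the highly
uneven per-tissue coverage of real EST collections (coverage is uniform
per site and library by default). Passing the simulation suites therefore
demonstrates the correctness and calibration of the statistics under
clean binomial sampling, not robustness to the messiness of real
alignment data.

## Numerical choices

* Two-sided mass comparisons use a relative tolerance of 1e-7 when
  deciding whether an outcome is "as extreme" as the observed table,
  avoiding floating-point misclassification of exactly tied
  probabilities.
* BH p-value ties are handled by the min-over-suffix adjusted-value
  construction, which makes adjusted values independent of input order
  and tie-stable.
* The editing-level percentage rounds half-up to one decimal
  (`floor(10x + 0.5) / 10`), matching how chromatogram peak ratios are
  conventionally reported; base R's `round()` rounds half to even and
  would turn 6.25 into 6.2 rather than 6.3.
* Degenerate inputs are defined, not errors: an empty pool gives p = 1,
  a single-tissue catalog yields zero tests with a warning, sequences
  shorter than a motif yield zero scan windows, and a zero-coverage
  simulation yields an empty observation table with its truth intact.
* ESE threshold semantics: a window scoring exactly the threshold is
  functional (score >= threshold). The same rule is applied before and
  after editing, so a lost hit is one whose edited-window score falls
  strictly below the threshold.

## Motif and annotation resources

The ESE scanner consumes standard position-weight-matrix files (four
base columns per motif position plus a threshold line). The four bundled
matrices carry the published widths and thresholds for SF2/ASF, SC35,
SRp40 and SRp55 but **synthetic placeholder weights** (marked as such in
the files); they make the annotation pipeline runnable out of the box
and should be replaced with the published matrices for real work. The
bundled ESS hexamer file is likewise a small partial set. Every
correctness test in the package uses toy matrices and explicit hexamer
sets, so no result depends on these bundled resources. Effect diffs are
symmetric: gained motifs are reported alongside destroyed ones, since
the symmetric diff is strictly more informative at no extra cost.

Genomic-to-transcript mapping (strand, splicing) is the caller's
responsibility: the scanners and the codon translator operate on
transcript-strand sequence with transcript coordinates, supplied through
the annotation command's sequence map. Analyses that would require
external trained predictors (splice-site models, phosphorylation,
signal-peptide or glycosylation predictors, miRNA/piRNA target
databases) are cataloged and fail with a clear error.

## Calibration, and what it does and does not guarantee

The package's simulation suites run at deliberately modest sizes — 1000
null replicates of 20 sites x 5 tissues x 100 observations per cell for
calibration, and 100 replicates of the same geometry with 200
observations per cell and two planted effects (editing level 0.6 against
a 0.05 background) for recovery — chosen so the suites complete quickly
while leaving Monte-Carlo error well below the effect sizes involved.

Two distinct error quantities matter, and only one of them is
controlled:

* **Within-tissue FDR.** BH at q = 0.05 bounds the expected
  false-discovery proportion within each tissue's family of tests. The
  null simulations measure a per-tissue family error of about 0.03,
  comfortably inside the bound (the discreteness of Fisher's test makes
  the procedure slightly conservative).
* **Experiment-wide error.** Nothing bounds the probability that *some*
  tissue somewhere produces a false call. With five tissue families the
  chance that a fully-null experiment yields at least one call is
  roughly `1 - (1 - 0.03)^5`, i.e. about one replicate in six, and the
  recovery simulations behave accordingly: the planted pairs are
  recovered essentially always, each individual non-truth pair is called
  in well under 1% of replicates, but a minority of replicates contain
  at least one false call somewhere among their ~100 tests. Users who
  need experiment-wide guarantees should lower `fdr_q` or apply BH to
  the pooled family across tissues instead; the per-tissue family is
  kept as the default because the tissue is the natural reporting unit
  here.

## Known limitations

* The pool ("all other tissues") is dominated by whatever tissues happen
  to be deeply sampled; a site's testability and power vary strongly
  with coverage, and uniform-coverage simulations are optimistic in this
  respect.
* Editing levels are treated as fixed per (site, tissue); no
  between-library overdispersion is modeled. Real libraries from the
  same tissue can differ (donor, disease state), which would inflate
  significance slightly in deeply covered tissues.
* The edited/unedited dichotomy discards partial chromatogram
  information; the peak-ratio estimator exists for exactly that use
  case but is separate from the screen.
* Bundled ESE weight matrices are placeholders (see above).
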