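# tisedit

Detection of tissue-specific A-to-I RNA editing sites from
expressed-sequence (EST/mRNA) data, with sequence-level effect annotation.

A-to-I RNA editing — deamination of adenosine to inosine by ADAR enzymes —
is read by sequencing machinery as an A-to-G change, so an edited
transcript shows G where the genome shows A. Given a catalog of known
editing sites and, for each site, the base observed in every expressed
sequence overlapping it (together with the cDNA library each sequence came
from), `tisedit` asks at which sites the editing level differs in one
tissue relative to all others. It is aimed at transcriptomics analysts who
have site catalogs and per-sequence base calls (e.g. derived from EST/mRNA
genome alignments) and want a reproducible, statistically controlled
screen for tissue specificity.

## The statistic

Every expressed sequence overlapping a site is classified **edited**
(transcript-strand G) or **unedited** (transcript-strand A); other letters
are treated as SNPs/sequencing errors and excluded. For a site *s* and a
tissue *T*, let

|            | edited | unedited |
|------------|--------|----------|
| tissue *T* | *a*    | *b*      |
| all other tissues (pooled) | *c* | *d* |

The p-value is Fisher's exact test on this 2x2 table (two-sided by
default, with a one-sided "enriched in *T*" option). Within each tissue,
the m p-values (one per testable site; a site is testable in *T* when at
least one edited sequence was observed there) are ranked ascending
p(1) <= ... <= p(m) and the Benjamini-Hochberg step-up rule rejects the
k hypotheses with rank up to the largest i such that p(i) <= (i/m) q,
with q = 0.05 by default. Reported "FDR corrected P values" are the BH
adjusted p-values, so a pair is called exactly when its adjusted p <= q.

Also provided:

* a chromatogram editing-level estimator, 100 G / (G + A) peak ratio
  rounded half-up to one decimal;
* effect annotation of an A-to-G edit: exonic splicing enhancer (ESE)
  position-weight-matrix scanning and before/after diffs, exonic splicing
  silencer (ESS) hexamer scanning and diffs, codon recoding under the
  standard genetic code, and per-transcript region classification
  (CDS / UTR / intron / intergenic);
* a seeded synthetic-data generator producing sites, libraries and
  observations with known planted tissue effects, so the whole screen can
  be validated end to end.

## Worked example

```r
library(tisedit)

cfg <- simulation_config(n_tissues = 4, libraries_per_tissue = 2,
                         n_sites = 6, obs_per_site_per_library = 120,
                         background_rate = 0.02,
                         effects = list(c(1, 2, 0.45)), seed = 2012)
ds      <- generate_dataset(cfg)            # sites, libraries, observations
catalog <- curate_libraries(ds$libraries)   # annotation -> tissue categories
counts  <- tabulate_observations(ds$observations, catalog)
fit     <- detect_tissue_specificity(counts, alternative = "greater")
summary(fit)
```

```
Tissue-specific A-to-I editing screen
  sites x tissues tabulated: 6 x 4 
  tests: 24  (per-tissue BH at q = 0.05 , greater Fisher)
  tissue-specific calls: 1 

Tests per tissue (m):
tissue01 tissue02 tissue03 tissue04 
       6        6        6        6 

Calls:
  chrom strand position   tissue   a   b  c   d        p adjusted_p
1  chr4      + 71113787 tissue02 120 120 14 706 7.61e-68 4.57e-67
```

The single call is the planted effect: site 1 was simulated at editing
level 0.45 in tissue 2 against a 2% background, and the screen finds 120
of 240 sequences edited in that tissue versus 14 of 720 in the pool
(adjusted p = 4.6e-67). `write_report(fit, "report.tsv")` serializes the
calls in the standard report layout.

The editing-level estimator works on chromatogram peak areas:

```r
editing_level_percent(151, 855)   # 17.7  (percent edited transcripts)
translate_codon_change("AGC", 1)  # Ser -> Gly recoding at protein pos 1
```

The same pipeline runs from files via the thin CLI in `exec/`:

```sh
exec/tisedit simulate --out-dir sim --n-tissues 3 --n-sites 4 --seed 9
exec/tisedit detect --sites sim/sites.tsv --libraries sim/libraries.tsv \
    --observations sim/observations.tsv --report sim/report.tsv
exec/tisedit report-check sim/report.tsv
```

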