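Package: tisedit
Title: Detection of Tissue-Specific A-to-I RNA Editing from Expressed-Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tissue-specific A-to-I RNA editing sites from
    expressed-sequence (EST/mRNA) observations overlapping a catalog of known
    editing sites. Each observation is classified as edited (transcript-strand
    guanosine) or unedited (adenosine), cDNA libraries are curated into tissue
    categories, and for every (site, tissue) pair a 2x2 table of edited and
    unedited counts in the tissue versus the pool of all other tissues is
    tested with Fisher's exact test; the Benjamini-Hochberg step-up procedure
    controls the false discovery rate within each tissue. Also provides a
    chromatogram peak-ratio editing-level estimator, sequence-level effect
    annotation of an A-to-G edit (exonic splicing enhancer matrix scanning,
    exonic splicing silencer hexamer scanning, codon recoding), and a seeded
    synthetic-data generator so the whole pipeline can be exercised and
    calibrated without external alignment data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
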