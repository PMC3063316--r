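# Shared builders for fixture-scale inputs, all constructed in code.

# A 490-library metadata table reproducing the curation totals: the 43
# tissue categories of the bundled tissue-distribution fixture with their
# per-tissue library counts (379 libraries), plus 111 decoy libraries that
# lack a tissue source or come from mixed samples.
make_full_library_table <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "table2_tissue_libraries.tsv",
                package = "tisedit"),
    stringsAsFactors = FALSE)
  ann <- rep(tab$tissue, tab$n_libraries)
  decoy_ann <- c(rep("", 55), rep("mixed", 40), rep("pooled organs", 16))
  data.frame(
    library_id = sprintf("LIB%03d", seq_len(length(ann) + length(decoy_ann))),
    tissue_annotation = c(ann, decoy_ann),
    stringsAsFactors = FALSE)
}

# 2-wide toy ESE matrix: weight 1 for A at position 1 and for G at
# position 2, zero elsewhere; window "AG" scores 2, "AA"/"CG" score 1.
toy_matrix <- function(threshold = 1.5, name = "toy") {
  w <- matrix(0, nrow = 2, ncol = 4)
  w[1, 1] <- 1  # A at position 1
  w[2, 3] <- 1  # G at position 2
  scoring_matrix(name, w, threshold)
}

# A small observation table from explicit base calls at one site.
obs_from_bases <- function(bases, library_id = "L1", chrom = "chr1",
                           strand = "+", position = 100L,
                           seq_prefix = "S") {
  data.frame(sequence_id = paste0(seq_prefix, seq_along(bases)),
             library_id = library_id, chrom = chrom, strand = strand,
             position = position, observed_base_plus = bases,
             stringsAsFactors = FALSE)
}
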