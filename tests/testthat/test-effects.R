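test_that("apply_edit substitutes exactly one A with G", {
  expect_equal(apply_edit("TAGGTA", 2), "TGGGTA")
  expect_equal(apply_edit("A", 1), "G")
  expect_error(apply_edit("TTAGGT", 4), "'G'")
  expect_error(apply_edit("TAG", 9), "outside")
})

test_that("ESE scanning scores every window against the threshold", {
  zero <- scoring_matrix("zero", matrix(0, 3, 4), 0.1)
  expect_equal(nrow(scan_ese("ACGTACGT", zero)), 0L)

  m <- toy_matrix(threshold = 1.5)
  hits <- scan_ese("AAG", m)   # windows: AA = 1, AG = 2
  expect_equal(hits$start, 2L)
  expect_equal(hits$score, 2)
  expect_equal(nrow(scan_ese("AAG", toy_matrix(threshold = 2.5))), 0L)
  # scores equal to the threshold are functional
  expect_equal(scan_ese("AAG", toy_matrix(threshold = 2))$start, 2L)
  # sequences shorter than the motif yield no hits, not an error
  expect_equal(nrow(scan_ese("A", m)), 0L)
})

test_that("scan examines exactly len - width + 1 windows", {
  set.seed(2)
  for (i in 1:20) {
    len <- sample(1:30, 1); width <- sample(1:8, 1)
    m <- scoring_matrix("all", matrix(1, width, 4), threshold = -1e9)
    hits <- scan_ese(random_dna(len), m)
    expect_equal(nrow(hits), max(0L, len - width + 1L))
  }
})

test_that("ESE diff reports hits destroyed or created at the edit", {
  m <- toy_matrix(threshold = 1.5)
  # editing position 2 turns window "AG" (2) into "GG" (1): hit lost;
  # the same edit turns window "AA" (1) into "AG" (2): hit gained
  d <- diff_ese("AAG", 2, m)
  expect_equal(d$lost$start, 2L)
  expect_equal(d$gained$start, 1L)
  # edit overlapping no above-threshold window changes nothing
  d2 <- diff_ese("TTATT", 3, m)
  expect_equal(nrow(d2$lost), 0L)
  expect_equal(nrow(d2$gained), 0L)
  # matrix rewarding G at position 1: below threshold before, above after
  wg <- matrix(0, 2, 4); wg[1, 3] <- 1
  mg <- scoring_matrix("gainer", wg, threshold = 1)
  d3 <- diff_ese("AAT", 2, mg)   # "AAT" -> "AGT": window "GT" scores 1
  expect_equal(d3$gained$start, 2L)
  expect_equal(nrow(d3$lost), 0L)
})

test_that("ESS hexamer scanning matches exact 6-mers", {
  set <- hexamer_set("toy", c("TTAGGT", "TAGGTA"))
  hits <- scan_ess("TTAGGTA", set)
  expect_equal(hits$start, c(1L, 2L))
  expect_equal(hits$motif, c("TTAGGT", "TAGGTA"))
  expect_equal(nrow(scan_ess("CCCCCCC", set)), 0L)
  expect_equal(nrow(scan_ess("TTAGG", set)), 0L)
  expect_error(hexamer_set("bad", "TTAGG"), "invalid hexamer")
})

test_that("ESS diff tracks silencers destroyed or created by the edit", {
  set <- hexamer_set("toy", c("TTAGGT", "TAGGTA"))
  d <- diff_ess("TTAGGTA", 3, set)   # "TTGGGTA" has no member hexamer
  expect_setequal(d$lost$motif, c("TTAGGT", "TAGGTA"))
  expect_equal(nrow(d$gained), 0L)

  gset <- hexamer_set("g", "GGGAGG")
  d2 <- diff_ess("GGAAGG", 3, gset)  # -> "GGGAGG": silencer gained
  expect_equal(d2$gained$start, 1L)
  expect_equal(d2$gained$motif, "GGGAGG")
  expect_equal(nrow(d2$lost), 0L)

  d3 <- diff_ess("TTAGGTAAAAAAAA", 14, set)  # edit far from any hit
  expect_equal(nrow(d3$lost), 0L)
  expect_equal(nrow(d3$gained), 0L)
})

test_that("ESS diff equals brute-force rescanning on random sequences", {
  set.seed(33)
  hexes <- c("GGGAGG", "TAGGTA", "TTAGGT", "CTTAGG", "AAGGGA", "TAAGGT")
  set <- hexamer_set("rand", hexes)
  tried <- 0
  while (tried < 80) {
    s <- random_dna(sample(6:30, 1), p = c(0.35, 0.05, 0.3, 0.3))
    a_pos <- which(strsplit(s, "")[[1]] == "A")
    if (!length(a_pos)) next
    pos <- a_pos[sample.int(length(a_pos), 1)]
    tried <- tried + 1
    d <- diff_ess(s, pos, set)
    orc <- oracle_diff_ess(s, pos, hexes)
    expect_equal(sort(paste(d$lost$start, d$lost$motif)), orc$lost)
    expect_equal(sort(paste(d$gained$start, d$gained$motif)), orc$gained)
  }
})

test_that("editing touches only windows spanning the edited position", {
  set.seed(44)
  m <- toy_matrix(threshold = 1.5)
  for (i in 1:40) {
    s <- random_dna(sample(8:30, 1))
    a_pos <- which(strsplit(s, "")[[1]] == "A")
    if (!length(a_pos)) next
    pos <- a_pos[sample.int(length(a_pos), 1)]
    before <- scan_ese(s, m)
    after <- scan_ese(apply_edit(s, pos), m)
    outside <- function(h) {
      o <- h[h$start > pos | h$start + 1L < pos, ]
      rownames(o) <- NULL
      o
    }
    expect_equal(outside(before), outside(after))
  }
})

test_that("codon recoding matches the genetic code on worked examples", {
  tr <- translate_codon_change("AGC", 1)     # the PARP-10 style Ser -> Gly
  expect_equal(tr$ref_aa3, "Ser")
  expect_equal(tr$alt_aa3, "Gly")
  expect_equal(tr$protein_position, 1)
  expect_false(tr$synonymous)

  syn <- translate_codon_change("GCA", 3)    # GCA -> GCG, both Ala
  expect_true(syn$synonymous)
  expect_equal(syn$ref_aa, syn$alt_aa)

  tr2 <- translate_codon_change("ATGTAA", 1) # ATG -> GTG, Met -> Val
  expect_equal(c(tr2$ref_aa, tr2$protein_position, tr2$alt_aa),
               c("M", "1", "V"))
  stop_loss <- translate_codon_change("TGA", 3)  # TGA -> TGG, Ter -> Trp
  expect_true(stop_loss$stop_loss)

  expect_error(translate_codon_change("ATGA", 4), "divisible by 3")
  expect_error(translate_codon_change("ATG", 2), "'T'")
})

test_that("all 64 codons agree with the Biostrings lookup oracle", {
  skip_if_not_installed("Biostrings")
  code <- Biostrings::GENETIC_CODE
  for (codon in names(code)) {
    for (i in 1:3) {
      if (substring(codon, i, i) != "A") next
      tr <- translate_codon_change(codon, i)
      edited <- codon
      substring(edited, i, i) <- "G"
      expect_equal(tr$ref_aa, unname(code[codon]))
      expect_equal(tr$alt_aa, unname(code[edited]))
      expect_equal(tr$protein_position, 1)
      expect_equal(tr$synonymous, unname(code[codon] == code[edited]))
    }
  }
})

test_that("region classification reports every overlapping transcript", {
  features <- data.frame(
    transcript_id = c("tx1", "tx1", "tx2"),
    chrom = "chr10", strand = "-",
    start = c(100L, 200L, 150L), end = c(180L, 300L, 260L),
    label = c("CDS", "3UTR", "intron"), stringsAsFactors = FALSE)
  site <- list(chrom = "chr10", strand = "-", position = 120L)
  expect_equal(classify_region(site, features)$label, "CDS")
  both <- classify_region(list(chrom = "chr10", strand = "-",
                               position = 250L), features)
  expect_setequal(both$label, c("3UTR", "intron"))
  off <- classify_region(list(chrom = "chr10", strand = "-",
                              position = 999L), features)
  expect_equal(off$label, "intergenic")
})

test_that("bundled motif resources load and anchor the published hexamers", {
  mats <- default_ese_matrices()
  expect_equal(length(mats), 4L)
  expect_setequal(vapply(mats, `[[`, character(1), "name"),
                  c("SF2/ASF", "SC35", "SRp40", "SRp55"))
  widths <- vapply(mats, `[[`, numeric(1), "width")
  names(widths) <- vapply(mats, `[[`, character(1), "name")
  expect_equal(widths[["SF2/ASF"]], 7)
  expect_equal(widths[["SC35"]], 8)
  expect_equal(widths[["SRp55"]], 6)
  hex <- default_ess_hexamers()
  expect_true(all(c("GGGAGG", "TAGGTA", "TTAGGT", "CTTAGG") %in%
                    hex$hexamers))
})
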