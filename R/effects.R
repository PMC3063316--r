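#' Apply an A-to-G edit to a transcript-strand sequence
#'
#' A-to-I editing is read as an A-to-G transition, so the edited sequence is
#' the input with the adenosine at `position` replaced by guanosine.
#'
#' @param sequence Transcript-strand DNA sequence (character scalar,
#'   alphabet A/C/G/T).
#' @param position 1-based position of the edited A.
#' @return The edited sequence.
#' @examples
#' apply_edit("TAGGTA", 2)  # "TGGGTA"
#' @export
apply_edit <- function(sequence, position) {
  sequence <- toupper(sequence)
  if (length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty character scalar")
  if (position < 1 || position > nchar(sequence))
    stop("position ", position, " outside sequence of length ",
         nchar(sequence))
  base <- substring(sequence, position, position)
  if (base != "A")
    stop("base at position ", position, " is '", base,
         "', not the required 'A'")
  paste0(substring(sequence, 1L, position - 1L), "G",
         substring(sequence, position + 1L, nchar(sequence)))
}

#' Read an ESE scoring matrix
#'
#' Reads a position weight matrix file: optional `#` comment lines, a
#' `threshold<TAB>value` line, a header line `A C G T`, then one row of
#' four scores per motif position.
#'
#' @param path Matrix file path.
#' @param name Motif name; defaults to the file's `# matrix:` comment or
#'   the file name.
#' @return A `"scoring_matrix"`: list with `name`, `width`, `weights`
#'   (width x 4 matrix, columns A, C, G, T), `threshold`.
#' @export
read_score_matrix <- function(path, name = NULL) {
  lines <- readLines(path)
  if (is.null(name)) {
    m <- grep("^#\\s*matrix:", lines, value = TRUE)
    name <- if (length(m)) trimws(sub("^#\\s*matrix:", "", m[1]))
            else basename(path)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  thr_line <- grep("^threshold\\b", lines)
  if (!length(thr_line)) stop("matrix file ", path, " has no threshold line")
  threshold <- as.numeric(strsplit(lines[thr_line[1]], "\t")[[1]][2])
  body <- lines[-seq_len(thr_line[1])]
  hdr <- strsplit(body[1], "\t")[[1]]
  if (!identical(toupper(trimws(hdr)), c("A", "C", "G", "T")))
    stop("matrix file ", path, " must have header columns A, C, G, T")
  rows <- do.call(rbind, lapply(body[-1], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  scoring_matrix(name, rows, threshold)
}

#' Construct an ESE scoring matrix
#'
#' @param name Motif name (e.g. "SF2/ASF").
#' @param weights Numeric width x 4 matrix of per-position scores,
#'   columns in A, C, G, T order.
#' @param threshold Minimum summed window score for a functional ESE hit.
#' @return A `"scoring_matrix"` object.
#' @export
scoring_matrix <- function(name, weights, threshold) {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4L || any(!is.finite(weights)))
    stop("weights must be a finite width x 4 matrix (A, C, G, T)")
  if (length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a finite scalar")
  colnames(weights) <- c("A", "C", "G", "T")
  structure(list(name = name, width = nrow(weights), weights = weights,
                 threshold = threshold),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat("ESE scoring matrix '", x$name, "': width ", x$width,
      ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

seq_to_idx <- function(sequence) {
  v <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(v, c("A", "C", "G", "T"))
  if (anyNA(idx))
    stop("sequence contains letters outside A/C/G/T: ",
         paste(unique(v[is.na(idx)]), collapse = ", "))
  idx
}

#' Scan a sequence for ESE matrix hits
#'
#' Scores every window of the matrix width as the sum of per-position,
#' per-base weights; windows scoring at or above the matrix threshold are
#' functional ESE hits.
#'
#' @param sequence Transcript-strand exon sequence.
#' @param matrix A `"scoring_matrix"`.
#' @return Data frame of hits: `start` (1-based), `motif`, `score`.
#'   Sequences shorter than the motif yield zero hits.
#' @export
scan_ese <- function(sequence, matrix) {
  if (!inherits(matrix, "scoring_matrix"))
    stop("matrix must be a scoring_matrix")
  hits0 <- data.frame(start = integer(0), motif = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  w <- matrix$width
  n <- nchar(sequence)
  if (n < w) return(hits0)
  idx <- seq_to_idx(sequence)
  starts <- seq_len(n - w + 1L)
  scores <- vapply(starts, function(s)
    sum(matrix$weights[cbind(seq_len(w), idx[s:(s + w - 1L)])]), numeric(1))
  hit <- scores >= matrix$threshold
  data.frame(start = starts[hit], motif = rep(matrix$name, sum(hit)),
             score = scores[hit], stringsAsFactors = FALSE)
}

#' ESE gain/loss caused by an edit
#'
#' Scans the sequence before and after [apply_edit()] with each matrix.
#' A hit present before editing, overlapping the edited position, whose
#' window score drops below the threshold after editing is a lost ESE
#' (the edit disrupts the enhancer); a hit overlapping the position that
#' only reaches the threshold after editing is a gained ESE.
#'
#' @param sequence Transcript-strand exon sequence with an A at `position`.
#' @param position 1-based edited position.
#' @param matrices A `"scoring_matrix"` or list of them.
#' @return List with data frames `lost` and `gained` (columns `start`,
#'   `motif`, `score`; the score of the state in which the hit exists).
#' @export
diff_ese <- function(sequence, position, matrices) {
  if (inherits(matrices, "scoring_matrix")) matrices <- list(matrices)
  edited <- apply_edit(sequence, position)
  lost <- list(); gained <- list()
  for (m in matrices) {
    before <- scan_ese(sequence, m)
    after <- scan_ese(edited, m)
    ov_b <- before$start <= position & position <= before$start + m$width - 1L
    ov_a <- after$start <= position & position <= after$start + m$width - 1L
    lost[[length(lost) + 1L]] <-
      before[ov_b & !(before$start %in% after$start[after$motif == m$name]), ,
             drop = FALSE]
    gained[[length(gained) + 1L]] <-
      after[ov_a & !(after$start %in% before$start[before$motif == m$name]), ,
            drop = FALSE]
  }
  list(lost = do.call(rbind, lost), gained = do.call(rbind, gained))
}

#' Read an ESS hexamer set
#'
#' One 6-base hexamer per line; `#` comment lines ignored.
#'
#' @param path Hexamer file path.
#' @param name Set label; defaults to the file name.
#' @return A `"hexamer_set"`: list with `name` and `hexamers`.
#' @export
read_hexamers <- function(path, name = NULL) {
  if (is.null(name)) name <- basename(path)
  lines <- toupper(trimws(readLines(path)))
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hexamer_set(name, lines)
}

#' Construct an ESS hexamer set
#'
#' @param name Set label (FAS-hex-3 style).
#' @param hexamers Character vector of 6-base strings over A/C/G/T.
#' @return A `"hexamer_set"` object.
#' @export
hexamer_set <- function(name, hexamers) {
  hexamers <- toupper(hexamers)
  bad <- hexamers[nchar(hexamers) != 6L | grepl("[^ACGT]", hexamers)]
  if (length(bad))
    stop("invalid hexamer(s): ", paste(unique(bad), collapse = ", "))
  structure(list(name = name, hexamers = unique(hexamers)),
            class = "hexamer_set")
}

#' Scan a sequence for ESS hexamer hits
#'
#' Every 6-base window exactly matching a set member is a hit.
#'
#' @param sequence Transcript-strand exon sequence.
#' @param set A `"hexamer_set"`.
#' @return Data frame of hits: `start` (1-based), `motif` (the hexamer).
#' @export
scan_ess <- function(sequence, set) {
  if (!inherits(set, "hexamer_set")) stop("set must be a hexamer_set")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 6L)
    return(data.frame(start = integer(0), motif = character(0),
                      stringsAsFactors = FALSE))
  starts <- seq_len(n - 5L)
  windows <- substring(sequence, starts, starts + 5L)
  hit <- windows %in% set$hexamers
  data.frame(start = starts[hit], motif = windows[hit],
             stringsAsFactors = FALSE)
}

#' ESS gain/loss caused by an edit
#'
#' Hexamer hits overlapping the edited position that disappear after the
#' A-to-G edit are lost ESSs; hits overlapping the position that only exist
#' in the edited sequence are gained.
#'
#' @inheritParams diff_ese
#' @param set A `"hexamer_set"`.
#' @return List with data frames `lost` and `gained` (`start`, `motif`).
#' @export
diff_ess <- function(sequence, position, set) {
  edited <- apply_edit(sequence, position)
  before <- scan_ess(sequence, set)
  after <- scan_ess(edited, set)
  ov_b <- before$start <= position & position <= before$start + 5L
  ov_a <- after$start <= position & position <= after$start + 5L
  key_b <- paste(before$start, before$motif)
  key_a <- paste(after$start, after$motif)
  list(lost = before[ov_b & !key_b %in% key_a, , drop = FALSE],
       gained = after[ov_a & !key_a %in% key_b, , drop = FALSE])
}

# standard genetic code, codon -> one-letter amino acid ('*' = stop)
GENETIC_CODE_1 <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

#' Amino-acid consequence of an A-to-G edit in a CDS
#'
#' Translates the codon containing the edited position before and after the
#' A-to-G substitution under the standard genetic code. The blood-specific
#' editing of PARP-10 is the canonical example: an AGC serine codon edited
#' at its first base becomes GGC, Ser -> Gly.
#'
#' @param cds Coding sequence (length divisible by 3, starts at the first
#'   codon position).
#' @param cds_position 1-based offset of the edited A within the CDS.
#' @return A list: `ref_aa`, `alt_aa` (one-letter, "*" for stop),
#'   `ref_aa3`, `alt_aa3` (three-letter), `protein_position`,
#'   `synonymous`, `stop_gain`, `stop_loss`.
#' @examples
#' translate_codon_change("AGC", 1)  # Ser -> Gly
#' @export
translate_codon_change <- function(cds, cds_position) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  if (cds_position < 1 || cds_position > n)
    stop("cds_position outside the CDS")
  edited <- apply_edit(cds, cds_position)   # validates the base is A
  codon_i <- ceiling(cds_position / 3)
  from <- 3L * (codon_i - 1L) + 1L
  ref_codon <- substring(cds, from, from + 2L)
  alt_codon <- substring(edited, from, from + 2L)
  if (grepl("[^ACGT]", ref_codon))
    stop("codon ", ref_codon, " contains letters outside A/C/G/T")
  ref_aa <- unname(GENETIC_CODE_1[ref_codon])
  alt_aa <- unname(GENETIC_CODE_1[alt_codon])
  list(ref_aa = ref_aa, alt_aa = alt_aa,
       ref_aa3 = unname(AA3[ref_aa]), alt_aa3 = unname(AA3[alt_aa]),
       protein_position = codon_i,
       synonymous = ref_aa == alt_aa,
       stop_gain = ref_aa != "*" && alt_aa == "*",
       stop_loss = ref_aa == "*" && alt_aa != "*")
}

#' Read transcript feature annotations
#'
#' Accepts a BED-like TSV with columns `transcript_id`, `chrom`, `strand`,
#' `start`, `end`, `label` (1-based closed intervals, labels among CDS,
#' 5UTR, 3UTR, intron, exon) or a GFF3 file (requires the rtracklayer
#' package; CDS / five_prime_UTR / three_prime_UTR / exon features, grouped
#' by their Parent attribute).
#'
#' @param path Feature file path.
#' @param format `"tsv"` (default) or `"gff3"`.
#' @return A data frame with the six columns above.
#' @export
read_features <- function(path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- read_tsv(path, c("transcript_id", "chrom", "strand", "start",
                           "end", "label"), "feature file")
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    df$strand <- normalize_strand(df$strand)
    return(df)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in%
    c("CDS", "five_prime_UTR", "three_prime_UTR", "exon", "intron")
  gr <- gr[keep]
  lab <- c(CDS = "CDS", five_prime_UTR = "5UTR", three_prime_UTR = "3UTR",
           exon = "exon", intron = "intron")[as.character(gr$type)]
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  data.frame(transcript_id = parent,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             label = unname(lab), stringsAsFactors = FALSE)
}

#' Locate an editing site within transcript features
#'
#' Reports, per overlapping transcript, the feature label (CDS, 5UTR, 3UTR,
#' intron, exon) containing the site; the same site may be 3'-UTR in one
#' isoform and intronic in another, and all labels are reported. A site
#' covered by no transcript on its chromosome and strand is "intergenic".
#'
#' @param site A one-row data frame (or list) with `chrom`, `strand`,
#'   `position`.
#' @param features Feature table from [read_features()].
#' @return Data frame with `transcript_id` and `label`; one row
#'   (`transcript_id = NA`, `label = "intergenic"`) when nothing overlaps.
#' @export
classify_region <- function(site, features) {
  hit <- features$chrom == site$chrom & features$strand == site$strand &
    features$start <= site$position & site$position <= features$end
  if (!any(hit))
    return(data.frame(transcript_id = NA_character_, label = "intergenic",
                      stringsAsFactors = FALSE))
  out <- unique(features[hit, c("transcript_id", "label"), drop = FALSE])
  rownames(out) <- NULL
  out
}
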