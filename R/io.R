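# Shared TSV helpers. All pipeline files are plain tab-separated text with a
# header line; coordinates are 1-based fully closed throughout the package,
# converted at this boundary when a 0-based half-open BED is read.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, required, what = "file") {
  if (!file.exists(path)) stop("cannot read ", what, ": ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

# the printed tables use a unicode minus for the reverse strand
normalize_strand <- function(x) {
  x <- trimws(x)
  x[x == "−"] <- "-"
  x
}

#' Read an editing-site catalog
#'
#' Reads a TSV of known A-to-I editing sites (`chrom`, `strand`, `position`,
#' optional `gene`; 1-based positions) or, with `format = "bed"`, a
#' headerless 6-column BED file (0-based half-open; converted on read).
#' Duplicate (chrom, strand, position) rows are collapsed to one and the
#' number of collapsed duplicates is reported via a message and stored in
#' the `"n_duplicates_collapsed"` attribute, yielding a non-redundant
#' catalog.
#'
#' @param path Path to the site file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return A data frame with columns `chrom`, `strand`, `position`
#'   (integer, 1-based), `gene`; class `c("site_catalog", "data.frame")`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tstrand\tposition\tgene",
#'              "chr6\t+\t52466294\tEFHC1",
#'              "chr6\t+\t52466294\tEFHC1"), f)
#' read_sites(f)  # collapses the duplicate row
#' @export
read_sites <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    if (!file.exists(path)) stop("cannot read site file: ", path)
    bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(bed) < 6)
      stop("BED site file must have 6 columns (chrom, start, end, name, ",
           "score, strand)")
    df <- data.frame(chrom = bed[[1]], strand = bed[[6]],
                     position = as.character(as.integer(bed[[2]]) + 1L),
                     gene = bed[[4]], stringsAsFactors = FALSE)
  } else {
    df <- read_tsv(path, c("chrom", "strand", "position"), "site file")
    if (!"gene" %in% names(df)) df$gene <- rep("", nrow(df))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      position = integer(0), gene = character(0),
                      stringsAsFactors = FALSE)
    return(new_site_catalog(out, 0L))
  }
  df$strand <- normalize_strand(df$strand)
  bad_strand <- which(!df$strand %in% c("+", "-"))
  if (length(bad_strand))
    stop("malformed strand '", df$strand[bad_strand[1]], "' at line ",
         bad_strand[1] + 1L, " of ", path)
  pos <- suppressWarnings(as.numeric(df$position))
  bad_pos <- which(!is.finite(pos) | pos < 1 | pos != floor(pos))
  if (length(bad_pos))
    stop("invalid position '", df$position[bad_pos[1]], "' at line ",
         bad_pos[1] + 1L, " of ", path)
  df$position <- as.integer(pos)

  key <- paste(df$chrom, df$strand, df$position, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  if (n_dup > 0L)
    message("read_sites: collapsed ", n_dup, " duplicate site record(s)")
  out <- df[!dup, c("chrom", "strand", "position", "gene"), drop = FALSE]
  rownames(out) <- NULL
  new_site_catalog(out, n_dup)
}

new_site_catalog <- function(df, n_dup) {
  attr(df, "n_duplicates_collapsed") <- as.integer(n_dup)
  class(df) <- c("site_catalog", "data.frame")
  df
}

#' Write an editing-site catalog
#'
#' Inverse of [read_sites()] (TSV form); `read_sites(write_sites(x))`
#' reproduces the catalog exactly.
#'
#' @param sites A site catalog data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(sites, path) {
  write_tsv(as.data.frame(sites)[, c("chrom", "strand", "position", "gene")],
            path)
  invisible(path)
}

#' Read a cDNA library metadata table
#'
#' Reads the `library_id` / `tissue_annotation` TSV (mirroring the content
#' of UCSC library dumps). Annotations are returned verbatim at this layer;
#' filtering and normalization belong to [curate_libraries()].
#'
#' @param path Path to the library TSV.
#' @return A data frame with columns `library_id`, `tissue_annotation`.
#' @export
read_libraries <- function(path) {
  df <- read_tsv(path, c("library_id", "tissue_annotation"), "library file")
  dup <- unique(df$library_id[duplicated(df$library_id)])
  if (length(dup))
    stop("duplicate library_id in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  df[, c("library_id", "tissue_annotation"), drop = FALSE]
}

#' Read per-sequence site observations
#'
#' Reads the observation TSV (`sequence_id`, `library_id`, `chrom`,
#' `strand`, `position`, `observed_base_plus`) and joins each row to the
#' site catalog by (chrom, strand, position). The catalog is authoritative
#' for strand: a row matching a catalog site's chrom and position but not
#' its strand is dropped as a strand conflict. Rows referencing unknown
#' sites or unknown libraries are also dropped; all drop counts are
#' messaged and stored in attributes (`"n_dropped_unknown_site"`,
#' `"n_dropped_unknown_library"`, `"n_dropped_strand_conflict"`).
#' Base letters are upper-cased.
#'
#' @param path Path to the observation TSV.
#' @param sites Site catalog from [read_sites()].
#' @param libraries Library table from [read_libraries()].
#' @return A data frame of retained observations with the input columns.
#' @export
read_observations <- function(path, sites, libraries) {
  df <- read_tsv(path, c("sequence_id", "library_id", "chrom", "strand",
                         "position", "observed_base_plus"),
                 "observation file")
  if (nrow(df) == 0L) {
    df$position <- integer(0)
    return(obs_with_counts(df, 0L, 0L, 0L))
  }
  df$strand <- normalize_strand(df$strand)
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos))
    stop("invalid position at line ", which(is.na(pos))[1] + 1L, " of ", path)
  df$position <- pos
  df$observed_base_plus <- toupper(trimws(df$observed_base_plus))

  full_key <- paste(df$chrom, df$strand, df$position, sep = "\r")
  cat_full <- paste(sites$chrom, sites$strand, sites$position, sep = "\r")
  loc_key <- paste(df$chrom, df$position, sep = "\r")
  cat_loc <- paste(sites$chrom, sites$position, sep = "\r")

  known_full <- full_key %in% cat_full
  strand_conflict <- !known_full & loc_key %in% cat_loc
  unknown_site <- !known_full & !strand_conflict
  unknown_lib <- !df$library_id %in% libraries$library_id

  keep <- known_full & !unknown_lib
  n_site <- sum(unknown_site)
  n_strand <- sum(strand_conflict)
  n_lib <- sum(unknown_lib & known_full)
  if (n_site + n_strand + n_lib > 0L)
    message("read_observations: dropped ", n_site, " unknown-site, ",
            n_strand, " strand-conflict and ", n_lib,
            " unknown-library row(s)")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  obs_with_counts(out, n_site, n_lib, n_strand)
}

obs_with_counts <- function(df, n_site, n_lib, n_strand) {
  attr(df, "n_dropped_unknown_site") <- as.integer(n_site)
  attr(df, "n_dropped_unknown_library") <- as.integer(n_lib)
  attr(df, "n_dropped_strand_conflict") <- as.integer(n_strand)
  df
}

#' Write a tissue-specificity report
#'
#' Serializes the calls of an [detect_tissue_specificity()] run as a TSV
#' with columns `tissue`, `chrom`, `strand`, `position`,
#' `fdr_corrected_p`, `gene`, sorted by tissue then position, with adjusted
#' p-values rendered to three significant digits.
#'
#' @param calls An `editing_specificity` object or its `calls` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(calls, path) {
  if (inherits(calls, "editing_specificity")) calls <- calls$calls
  if (!"gene" %in% names(calls)) calls$gene <- rep("", nrow(calls))
  out <- data.frame(tissue = calls$tissue, chrom = calls$chrom,
                    strand = calls$strand, position = calls$position,
                    fdr_corrected_p = sprintf("%.3g", calls$adjusted_p),
                    gene = calls$gene, stringsAsFactors = FALSE)
  out <- out[order(out$tissue, out$position), , drop = FALSE]
  write_tsv(out, path)
  invisible(path)
}

#' Read a tissue-specificity report
#'
#' Parses a report written by [write_report()] (or transcribed in the same
#' layout) back into a data frame with a numeric `fdr_corrected_p` column.
#'
#' @param path Path to the report TSV.
#' @return A data frame with columns `tissue`, `chrom`, `strand`,
#'   `position`, `fdr_corrected_p`, `gene`.
#' @export
read_report <- function(path) {
  df <- read_tsv(path, c("tissue", "chrom", "strand", "position",
                         "fdr_corrected_p"), "report file")
  df$strand <- normalize_strand(df$strand)
  df$position <- as.integer(df$position)
  df$fdr_corrected_p <- as.numeric(df$fdr_corrected_p)
  if (!"gene" %in% names(df)) df$gene <- ""
  df
}

#' Read an annotation merge map
#'
#' Two-column TSV mapping a normalized library tissue annotation to a
#' curated tissue category, used by [curate_libraries()] to merge synonyms
#' and collapse normal/cancerous qualifiers to one category.
#'
#' @param path Path to the merge-map TSV (columns `annotation`, `category`).
#' @return A named character vector (names are normalized annotations).
#' @export
read_merge_map <- function(path) {
  df <- read_tsv(path, c("annotation", "category"), "merge map")
  ann <- tolower(trimws(df$annotation))
  dup <- ann[duplicated(ann)]
  conflicting <- unique(dup[vapply(dup, function(a)
    length(unique(df$category[ann == a])) > 1L, logical(1))])
  if (length(conflicting))
    stop("merge map assigns multiple categories to: ",
         paste(conflicting, collapse = ", "))
  stats::setNames(trimws(df$category), ann)[!duplicated(ann)]
}
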