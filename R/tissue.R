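#' Curate cDNA libraries into tissue categories
#'
#' Applies the two library-level exclusion rules — no clear tissue source
#' (empty or whitespace-only annotation) and mixed tissue samples
#' (annotation matching one of the `mixed_patterns`) — then normalizes the
#' remaining annotations (trimmed, case-folded) and merges them into tissue
#' categories, either through an explicit merge map (so e.g. "brain" and
#' "brain tumor" collapse to one "brain" category covering normal and
#' cancerous samples) or by normalized identity.
#'
#' @param libraries Library table from [read_libraries()] (columns
#'   `library_id`, `tissue_annotation`).
#' @param merge_map Optional named character vector from [read_merge_map()]:
#'   names are normalized annotations, values the category each maps to.
#' @param mixed_patterns Character vector of substrings (matched
#'   case-insensitively) marking a mixed/pooled sample. Default
#'   `c("mix", "pool")`.
#' @return An object of class `"tissue_catalog"`: a list with
#'   `assignments` (data frame `library_id`, `category`) and `excluded`
#'   (data frame `library_id`, `reason`).
#' @examples
#' libs <- data.frame(library_id = c("L1", "L2", "L3", "L4"),
#'                    tissue_annotation = c("brain", "Brain ", "mixed", ""))
#' curate_libraries(libs)
#' @export
curate_libraries <- function(libraries, merge_map = NULL,
                             mixed_patterns = c("mix", "pool")) {
  if (!all(c("library_id", "tissue_annotation") %in% names(libraries)))
    stop("libraries must have columns library_id and tissue_annotation")
  if (!is.null(merge_map)) {
    if (is.null(names(merge_map)) || any(names(merge_map) == ""))
      stop("merge_map must be a named character vector")
    nm <- tolower(trimws(names(merge_map)))
    conflict <- unique(nm[duplicated(nm)][vapply(
      nm[duplicated(nm)],
      function(a) length(unique(merge_map[nm == a])) > 1L, logical(1))])
    if (length(conflict))
      stop("merge_map assigns multiple categories to: ",
           paste(conflict, collapse = ", "))
    merge_map <- stats::setNames(unname(merge_map), nm)[!duplicated(nm)]
  }

  ann <- libraries$tissue_annotation
  ann[is.na(ann)] <- ""
  norm <- tolower(trimws(ann))

  no_source <- norm == ""
  mixed <- !no_source & Reduce(`|`, lapply(mixed_patterns, function(p)
    grepl(p, norm, fixed = TRUE)), rep(FALSE, length(norm)))

  excluded <- data.frame(
    library_id = libraries$library_id[no_source | mixed],
    reason = ifelse(no_source[no_source | mixed], "no tissue source",
                    "mixed tissue sample"),
    stringsAsFactors = FALSE
  )

  keep <- !(no_source | mixed)
  category <- norm[keep]
  if (!is.null(merge_map)) {
    mapped <- unname(merge_map[category])
    category <- ifelse(is.na(mapped), category, mapped)
  }
  assignments <- data.frame(library_id = libraries$library_id[keep],
                            category = category, stringsAsFactors = FALSE)
  structure(list(assignments = assignments, excluded = excluded),
            class = "tissue_catalog")
}

#' @export
print.tissue_catalog <- function(x, ...) {
  cat("Tissue catalog:", nrow(x$assignments), "libraries in",
      length(unique(x$assignments$category)), "categories;",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded))
    print(table(x$excluded$reason))
  invisible(x)
}

#' Write a library exclusion summary
#'
#' @param catalog A `"tissue_catalog"`.
#' @param path Output TSV path (columns `library_id`, `reason`).
#' @return Invisibly, `path`.
#' @export
write_exclusions <- function(catalog, path) {
  write_tsv(catalog$excluded, path)
  invisible(path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Classify an observed base as edited or unedited
#'
#' The base observed on the genome plus strand is first converted to the
#' transcript (site) strand — complemented when the site strand is "-" —
#' and then classified: transcript-strand G is edited (A-to-I editing reads
#' as A-to-G), A is unedited, and any other letter (C, T, N: a SNP or a
#' sequencing error at the site) is "other" and excluded from both counts
#' downstream.
#'
#' @param strand Site strand, "+" or "-" (vectorized).
#' @param observed_base_plus Base on the genome plus strand, one of
#'   A, C, G, T, N (vectorized, case-insensitive).
#' @return A character vector over \{"edited", "unedited", "other"\}.
#' @examples
#' classify_base("+", "G")  # edited
#' classify_base("-", "C")  # edited: transcript-strand G
#' classify_base("+", "T")  # other
#' @export
classify_base <- function(strand, observed_base_plus) {
  base <- toupper(observed_base_plus)
  if (any(!base %in% names(COMPLEMENT)))
    stop("invalid base letter(s): ",
         paste(unique(base[!base %in% names(COMPLEMENT)]), collapse = ", "))
  if (any(!strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  tx <- ifelse(strand == "-", COMPLEMENT[base], base)
  out <- rep("other", length(tx))
  out[tx == "G"] <- "edited"
  out[tx == "A"] <- "unedited"
  out
}

#' Tabulate edited/unedited counts per site and tissue
#'
#' Classifies every observation with [classify_base()], maps its library to
#' a curated tissue category, and counts edited and unedited sequences per
#' (site, tissue) pair. Observations from excluded libraries, observations
#' classified "other", and duplicate observations of the same sequence at
#' the same site (first kept) contribute to nothing; their totals are
#' messaged and stored in attributes (`"n_omitted_excluded_library"`,
#' `"n_omitted_other_base"`, `"n_omitted_duplicate_sequence"`). Every
#' (site, tissue) pair with at least one retained observation appears in
#' the output.
#'
#' @param observations Observation data frame (from [read_observations()]
#'   or a `synthetic_dataset`).
#' @param catalog A `"tissue_catalog"` from [curate_libraries()].
#' @return A data frame with columns `chrom`, `strand`, `position`,
#'   `tissue`, `edited`, `unedited`, ready for
#'   [detect_tissue_specificity()].
#' @export
tabulate_observations <- function(observations, catalog) {
  if (!inherits(catalog, "tissue_catalog"))
    stop("catalog must come from curate_libraries()")
  obs <- as.data.frame(observations)
  needed <- c("sequence_id", "library_id", "chrom", "strand", "position",
              "observed_base_plus")
  missing_cols <- setdiff(needed, names(obs))
  if (length(missing_cols))
    stop("observations missing columns: ",
         paste(missing_cols, collapse = ", "))

  empty <- data.frame(chrom = character(0), strand = character(0),
                      position = integer(0), tissue = character(0),
                      edited = integer(0), unedited = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(obs) == 0L) return(counts_with_attrs(empty, 0L, 0L, 0L))

  tissue <- catalog$assignments$category[
    match(obs$library_id, catalog$assignments$library_id)]
  from_excluded <- is.na(tissue)
  site_key <- paste(obs$chrom, obs$strand, obs$position, sep = "\r")
  dup_seq <- duplicated(paste(obs$sequence_id, site_key, sep = "\r"))

  status <- classify_base(obs$strand, obs$observed_base_plus)
  keep <- !from_excluded & !dup_seq & status != "other"

  n_excl <- sum(from_excluded & !dup_seq)
  n_dup <- sum(dup_seq)
  n_other <- sum(status == "other" & !from_excluded & !dup_seq)
  if (n_excl + n_dup + n_other > 0L)
    message("tabulate_observations: omitted ", n_excl,
            " excluded-library, ", n_dup, " duplicate-sequence and ",
            n_other, " non-A/G observation(s)")
  if (!any(keep)) return(counts_with_attrs(empty, n_excl, n_other, n_dup))

  k <- data.frame(chrom = obs$chrom[keep], strand = obs$strand[keep],
                  position = obs$position[keep], tissue = tissue[keep],
                  edited = as.integer(status[keep] == "edited"),
                  stringsAsFactors = FALSE)
  grp <- paste(k$chrom, k$strand, k$position, k$tissue, sep = "\r")
  first <- !duplicated(grp)
  ed <- rowsum(k$edited, grp)
  tot <- rowsum(rep(1L, nrow(k)), grp)
  idx <- match(grp[first], rownames(ed))
  out <- data.frame(chrom = k$chrom[first], strand = k$strand[first],
                    position = k$position[first], tissue = k$tissue[first],
                    edited = as.integer(ed[idx, 1L]),
                    unedited = as.integer(tot[idx, 1L] - ed[idx, 1L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$position, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  counts_with_attrs(out, n_excl, n_other, n_dup)
}

counts_with_attrs <- function(df, n_excl, n_other, n_dup) {
  attr(df, "n_omitted_excluded_library") <- as.integer(n_excl)
  attr(df, "n_omitted_other_base") <- as.integer(n_other)
  attr(df, "n_omitted_duplicate_sequence") <- as.integer(n_dup)
  df
}
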