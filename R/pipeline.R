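#' Load a pipeline configuration
#'
#' Reads a flat key-value YAML document and merges command-line style
#' overrides on top (overrides win). Recognized keys: `sites`, `libraries`,
#' `observations`, `merge_map`, `features`, `matrices` (directory or vector
#' of matrix files), `hexamers`, `sequences` (FASTA), `sequence_map`,
#' `report`, `fdr_q`, `sidedness` (`two_sided` or `greater`),
#' `min_edited_in_tissue`, `out_dir`, `seed`, plus the
#' [simulation_config()] fields for the simulate command.
#'
#' @param path Optional YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A named list of class `"pipeline_config"`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else list()
  for (k in names(overrides))
    if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  if (!is.null(cfg$fdr_q)) {
    cfg$fdr_q <- as.numeric(cfg$fdr_q)
    if (!is.finite(cfg$fdr_q) || cfg$fdr_q <= 0 || cfg$fdr_q >= 1)
      stop("fdr_q must be in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

cfg_get <- function(cfg, key, default = NULL) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

#' Run the simulate command
#'
#' Builds a [simulation_config()] from the configuration, generates a
#' dataset and writes the four dataset TSVs (sites, libraries,
#' observations, truth) into `out_dir`.
#'
#' @param config A `"pipeline_config"` (or path to a YAML file).
#' @return Invisibly, the named vector of written file paths.
#' @export
run_simulate <- function(config) {
  if (is.character(config)) config <- load_config(config)
  eff <- cfg_get(config, "effects", list())
  if (length(eff) && !is.list(eff)) eff <- list(eff)
  sim <- simulation_config(
    n_tissues = cfg_get(config, "n_tissues", 2L),
    libraries_per_tissue = cfg_get(config, "libraries_per_tissue", 1L),
    n_sites = cfg_get(config, "n_sites", 10L),
    obs_per_site_per_library = cfg_get(config, "obs_per_site_per_library",
                                       100L),
    background_rate = cfg_get(config, "background_rate", 0.05),
    effects = eff,
    n_decoy_libraries = cfg_get(config, "n_decoy_libraries", 0L),
    seed = cfg_get(config, "seed", 1L))
  ds <- generate_dataset(sim)
  out <- cfg_get(config, "out_dir", ".")
  paths <- write_dataset(ds, out)
  message("run_simulate: wrote ", nrow(ds$observations),
          " observations to ", out)
  invisible(paths)
}

#' Run the detection command
#'
#' Executes the full screen from files: read sites, libraries and
#' observations, curate libraries, tabulate edited/unedited counts, run
#' the per-tissue Fisher + Benjamini-Hochberg detection, and write the
#' report. Library exclusion counts, omitted-observation counts and the
#' per-tissue number of tests are reported through messages.
#'
#' @param config A `"pipeline_config"` (or path to a YAML file) with at
#'   least `sites`, `libraries`, `observations` and `report` keys.
#' @return Invisibly, the `"editing_specificity"` object.
#' @export
run_detect <- function(config) {
  if (is.character(config)) config <- load_config(config)
  for (k in c("sites", "libraries", "observations", "report"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  sites <- read_sites(config$sites)
  libraries <- read_libraries(config$libraries)
  merge_map <- if (!is.null(config$merge_map))
    read_merge_map(config$merge_map) else NULL
  observations <- read_observations(config$observations, sites, libraries)
  catalog <- curate_libraries(libraries, merge_map = merge_map)
  message("run_detect: ", nrow(catalog$assignments), " libraries in ",
          length(unique(catalog$assignments$category)), " tissues; ",
          nrow(catalog$excluded), " excluded")
  counts <- tabulate_observations(observations, catalog)
  fit <- detect_tissue_specificity(
    counts,
    q = cfg_get(config, "fdr_q", 0.05),
    alternative = if (identical(cfg_get(config, "sidedness", "two_sided"),
                                "greater")) "greater" else "two.sided",
    min_edited_in_tissue = cfg_get(config, "min_edited_in_tissue", 1L))
  if (length(fit$m_per_tissue))
    message("run_detect: tests per tissue: ",
            paste(names(fit$m_per_tissue), fit$m_per_tissue, sep = "=",
                  collapse = ", "))
  write_report(fit, config$report)
  message("run_detect: ", nrow(fit$calls), " tissue-specific call(s) ",
          "written to ", config$report)
  invisible(fit)
}

#' Run the annotation command
#'
#' Annotates each tissue-specific call with its sequence-level effects:
#' feature region labels, ESE matrix gains/losses, ESS hexamer
#' gains/losses and, when a CDS position is supplied, the amino-acid
#' change. Genomic-to-transcript mapping is supplied by the caller as a
#' sequence map TSV (`chrom`, `strand`, `position`, `seq_id`,
#' `seq_position`, optional `cds_position`) pointing into the FASTA of
#' transcript-strand sequences. Calls with no mapped sequence are flagged
#' and the run continues.
#'
#' @param config A `"pipeline_config"` (or YAML path) with `report` (the
#'   detection report to annotate), `sequences`, `sequence_map`, and
#'   optionally `matrices`, `hexamers`, `features`, `effects_out`.
#' @return Invisibly, the annotation data frame.
#' @export
run_annotate <- function(config) {
  if (is.character(config)) config <- load_config(config)
  for (k in c("report", "sequences", "sequence_map"))
    if (is.null(config[[k]])) stop("config key '", k, "' is required")
  calls <- read_report(config$report)
  seqs <- read_fasta(config$sequences)
  smap <- read_tsv(config$sequence_map,
                   c("chrom", "strand", "position", "seq_id",
                     "seq_position"), "sequence map")
  smap$position <- as.integer(smap$position)
  smap$seq_position <- as.integer(smap$seq_position)
  smap$strand <- normalize_strand(smap$strand)
  has_cds <- "cds_position" %in% names(smap)

  matrices <- if (!is.null(config$matrices)) {
    paths <- config$matrices
    if (length(paths) == 1L && dir.exists(paths))
      paths <- list.files(paths, pattern = "\\.tsv$", full.names = TRUE)
    lapply(paths, read_score_matrix)
  } else default_ese_matrices()
  hexamers <- if (!is.null(config$hexamers)) read_hexamers(config$hexamers)
              else default_ess_hexamers()
  features <- if (!is.null(config$features)) read_features(config$features)
              else NULL

  rows <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    base <- data.frame(tissue = call$tissue, chrom = call$chrom,
                       strand = call$strand, position = call$position,
                       stringsAsFactors = FALSE)
    mi <- which(smap$chrom == call$chrom & smap$strand == call$strand &
                smap$position == call$position)
    region <- if (!is.null(features)) {
      paste(apply(classify_region(call, features), 1L, paste,
                  collapse = ":"), collapse = ",")
    } else ""
    if (!length(mi) || !smap$seq_id[mi[1]] %in% names(seqs)) {
      return(cbind(base, data.frame(status = "no_sequence", region = region,
                                    lost_ese = "", gained_ese = "",
                                    lost_ess = "", gained_ess = "",
                                    aa_change = "",
                                    stringsAsFactors = FALSE)))
    }
    m <- smap[mi[1], ]
    sequence <- seqs[[m$seq_id]]
    ese <- diff_ese(sequence, m$seq_position, matrices)
    ess <- diff_ess(sequence, m$seq_position, hexamers)
    fmt <- function(h) if (is.null(h) || nrow(h) == 0L) "" else
      paste(h$motif, h$start, sep = "@", collapse = ",")
    aa <- ""
    if (has_cds && !is.na(m$cds_position) && nzchar(m$cds_position)) {
      tr <- translate_codon_change(sequence, as.integer(m$cds_position))
      aa <- paste0(tr$ref_aa3, tr$protein_position, tr$alt_aa3,
                   if (tr$synonymous) " (synonymous)" else "")
    }
    cbind(base, data.frame(status = "ok", region = region,
                           lost_ese = fmt(ese$lost),
                           gained_ese = fmt(ese$gained),
                           lost_ess = fmt(ess$lost),
                           gained_ess = fmt(ess$gained),
                           aa_change = aa, stringsAsFactors = FALSE))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tissue = character(0), chrom = character(0),
               strand = character(0), position = integer(0),
               status = character(0), region = character(0),
               lost_ese = character(0), gained_ese = character(0),
               lost_ess = character(0), gained_ess = character(0),
               aa_change = character(0), stringsAsFactors = FALSE)
  if (!is.null(config$effects_out)) write_tsv(out, config$effects_out)
  n_flag <- sum(out$status != "ok")
  if (n_flag) message("run_annotate: ", n_flag,
                      " call(s) without a mapped sequence")
  invisible(out)
}

# minimal FASTA reader for transcript-strand sequences (plain text, no
# external index needed)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  id <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(as.list(toupper(gsub("\\s", "", seqs))), id)
}

#' Validate a report file's schema
#'
#' Checks that a report TSV has the expected columns, well-formed strands,
#' positive integer positions and adjusted p-values in (0, 1].
#'
#' @param path Report file path.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
check_report <- function(path) {
  df <- read_report(path)
  if (any(!df$strand %in% c("+", "-")))
    stop("report has malformed strand values")
  if (any(is.na(df$position) | df$position < 1))
    stop("report has invalid positions")
  if (any(!is.finite(df$fdr_corrected_p) | df$fdr_corrected_p <= 0 |
          df$fdr_corrected_p > 1))
    stop("report has adjusted p-values outside (0, 1]")
  invisible(TRUE)
}

#' Bundled ESE matrices (synthetic placeholder weights)
#'
#' Loads the four SR-protein scoring matrices shipped with the package
#' (SF2/ASF, SC35, SRp40, SRp55). The motif widths and score thresholds
#' follow the published ESEfinder values; the per-position weights are
#' synthetic placeholders (the published weight tables are not
#' redistributed here) and should be replaced with the published matrices
#' for real annotation work. All correctness tests use toy matrices, so no
#' result in this package depends on these weights.
#'
#' @return A list of four `"scoring_matrix"` objects.
#' @export
default_ese_matrices <- function() {
  dir <- system.file("extdata", "ese_matrices", package = "tisedit")
  lapply(list.files(dir, pattern = "\\.tsv$", full.names = TRUE),
         read_score_matrix)
}

#' Bundled ESS hexamer subset
#'
#' Loads the bundled exonic-splicing-silencer hexamer file, a partial
#' FAS-hex-3 style set. Replace with the full published hexamer list for
#' real annotation work.
#'
#' @return A `"hexamer_set"`.
#' @export
default_ess_hexamers <- function() {
  read_hexamers(system.file("extdata", "fas_hex3_subset.txt",
                            package = "tisedit"),
                name = "FAS-hex-3 (subset)")
}

# Effect analyses that depend on external trained predictors are
# deliberately not provided; fail with a clear catalog entry.
UNSUPPORTED_PREDICTIONS <- c(
  "splice_site", "phosphorylation", "signal_peptide", "propeptide_cleavage",
  "n_glycosylation", "o_glycosylation", "c_glycosylation",
  "mirna_target", "pirna")

#' Unsupported effect predictions
#'
#' Predictions that require external trained predictors or external target
#' databases (splice-site modeling, phosphorylation, signal peptide,
#' propeptide cleavage, N/O/C-glycosylation, miRNA/piRNA target mapping)
#' are out of scope; calling this with any of those names raises a clear
#' error listing what is supported instead.
#'
#' @param name Prediction name.
#' @return Never returns; always stops.
#' @export
unsupported_prediction <- function(name) {
  if (name %in% UNSUPPORTED_PREDICTIONS)
    stop("prediction '", name, "' requires an external trained predictor ",
         "or database and is not supported; supported analyses are ESE ",
         "matrix diffs, ESS hexamer diffs, codon recoding and feature ",
         "region classification")
  stop("unknown prediction '", name, "'")
}
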