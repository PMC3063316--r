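#' Simulation configuration for synthetic editing datasets
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The generator emulates the statistical structure of the real inputs: a
#' catalog of known A-to-I sites, a set of cDNA libraries grouped by tissue,
#' and per-site expressed-sequence observations whose edited counts are
#' binomial draws at a background editing level, elevated to a
#' tissue-specific level for the configured (site, tissue) effects.
#'
#' @param n_tissues Number of tissues (positive integer).
#' @param libraries_per_tissue Libraries per tissue (positive integer).
#' @param n_sites Number of editing sites (positive integer).
#' @param obs_per_site_per_library Expressed-sequence coverage per site per
#'   library (non-negative integer).
#' @param background_rate Editing probability in non-specific tissues, in
#'   `[0, 1]`.
#' @param effects List of tissue-specific effects, each a length-3 vector
#'   `c(site_index, tissue_index, rate)` with 1-based indices and rate in
#'   `[0, 1]`.
#' @param n_decoy_libraries Number of decoy libraries with "mixed" or empty
#'   tissue annotation, to exercise the curation filters (non-negative).
#' @param seed Integer seed; identical configuration and seed yield an
#'   identical dataset.
#' @return A validated list of class `"simulation_config"`.
#' @examples
#' simulation_config(n_tissues = 2, libraries_per_tissue = 1, n_sites = 1,
#'                   obs_per_site_per_library = 100, background_rate = 0.1,
#'                   effects = list(c(1, 1, 0.6)), seed = 1)
#' @export
simulation_config <- function(n_tissues, libraries_per_tissue, n_sites,
                              obs_per_site_per_library, background_rate,
                              effects = list(), n_decoy_libraries = 0L,
                              seed = 1L) {
  chk_count <- function(x, name, min = 1) {
    if (length(x) != 1L || !is.finite(x) || x != floor(x) || x < min)
      stop("invalid field '", name, "': must be an integer >= ", min)
    as.integer(x)
  }
  chk_rate <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop("invalid field '", name, "': must be a probability in [0, 1]")
    as.numeric(x)
  }
  cfg <- list(
    n_tissues = chk_count(n_tissues, "n_tissues"),
    libraries_per_tissue = chk_count(libraries_per_tissue,
                                     "libraries_per_tissue"),
    n_sites = chk_count(n_sites, "n_sites"),
    obs_per_site_per_library = chk_count(obs_per_site_per_library,
                                         "obs_per_site_per_library", min = 0),
    background_rate = chk_rate(background_rate, "background_rate"),
    effects = effects,
    n_decoy_libraries = chk_count(n_decoy_libraries, "n_decoy_libraries",
                                  min = 0),
    seed = chk_count(seed, "seed", min = -.Machine$integer.max)
  )
  if (!is.list(effects)) stop("invalid field 'effects': must be a list")
  for (e in effects) {
    if (length(e) != 3L || any(!is.finite(e)))
      stop("invalid field 'effects': each effect is c(site, tissue, rate)")
    if (e[1] != floor(e[1]) || e[1] < 1 || e[1] > cfg$n_sites)
      stop("invalid field 'effects': site index ", e[1], " out of range")
    if (e[2] != floor(e[2]) || e[2] < 1 || e[2] > cfg$n_tissues)
      stop("invalid field 'effects': tissue index ", e[2], " out of range")
    if (e[3] < 0 || e[3] > 1)
      stop("invalid field 'effects': rate ", e[3], " outside [0, 1]")
  }
  eff_key <- vapply(effects, function(e) paste(e[1], e[2]), character(1))
  if (anyDuplicated(eff_key))
    stop("invalid field 'effects': duplicate (site, tissue) pair")
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a synthetic editing dataset
#'
#' Draws, for every (site, library) pair, `obs_per_site_per_library`
#' expressed-sequence observations whose edited status is Bernoulli with
#' success probability equal to the configured effect rate when the
#' library's tissue carries an effect at that site, and the background rate
#' otherwise. Observed bases are emitted on the genome plus strand honoring
#' each site's strand (an edited sequence reads G on the transcript strand),
#' so the downstream strand-aware classifier is exercised. Decoy libraries
#' are annotated "mixed" or "" (alternating) and receive background-rate
#' observations; the curation step is expected to drop them.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"synthetic_dataset"` with data frames `sites`
#'   (chrom, strand, position, gene), `libraries` (library_id,
#'   tissue_annotation), `observations` (sequence_id, library_id, chrom,
#'   strand, position, observed_base_plus), and `truth` (site columns plus
#'   tissue and rate for every genuinely tissue-specific pair).
#' @examples
#' cfg <- simulation_config(2, 1, 2, 50, 0.05,
#'                          effects = list(c(1, 1, 0.6)), seed = 42)
#' ds <- generate_dataset(cfg)
#' head(ds$observations)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  n_sites <- config$n_sites
  chroms <- paste0("chr", c(1:22, "X"))
  sites <- data.frame(
    chrom = sample(chroms, n_sites, replace = TRUE),
    strand = sample(c("+", "-"), n_sites, replace = TRUE),
    position = sample.int(2e8L, n_sites, replace = FALSE),
    gene = sprintf("GENE%03d", seq_len(n_sites)),
    stringsAsFactors = FALSE
  )

  tissue_names <- sprintf("tissue%02d", seq_len(config$n_tissues))
  lib_tissue_idx <- rep(seq_len(config$n_tissues),
                        each = config$libraries_per_tissue)
  libraries <- data.frame(
    library_id = sprintf("LIB%04d", seq_along(lib_tissue_idx)),
    tissue_annotation = tissue_names[lib_tissue_idx],
    stringsAsFactors = FALSE
  )
  if (config$n_decoy_libraries > 0L) {
    decoys <- data.frame(
      library_id = sprintf("DECOY%03d", seq_len(config$n_decoy_libraries)),
      tissue_annotation = rep_len(c("mixed", ""), config$n_decoy_libraries),
      stringsAsFactors = FALSE
    )
    libraries <- rbind(libraries, decoys)
  }

  # rate matrix: sites x libraries (decoys stay at background)
  n_libs <- nrow(libraries)
  rates <- matrix(config$background_rate, nrow = n_sites, ncol = n_libs)
  for (e in config$effects) {
    lib_cols <- which(c(lib_tissue_idx, rep(NA, config$n_decoy_libraries)) ==
                      e[2])
    rates[e[1], lib_cols] <- e[3]
  }

  n_obs <- config$obs_per_site_per_library
  if (n_obs > 0L) {
    site_i <- rep(rep(seq_len(n_sites), times = n_libs), each = n_obs)
    lib_i  <- rep(seq_len(n_libs), each = n_sites * n_obs)
    edited <- stats::rbinom(length(site_i), 1L,
                            rates[cbind(site_i, lib_i)]) == 1L
    strand <- sites$strand[site_i]
    base <- ifelse(edited,
                   ifelse(strand == "+", "G", "C"),
                   ifelse(strand == "+", "A", "T"))
    observations <- data.frame(
      sequence_id = sprintf("EST%07d", seq_along(site_i)),
      library_id = libraries$library_id[lib_i],
      chrom = sites$chrom[site_i],
      strand = strand,
      position = sites$position[site_i],
      observed_base_plus = base,
      stringsAsFactors = FALSE
    )
  } else {
    observations <- data.frame(
      sequence_id = character(0), library_id = character(0),
      chrom = character(0), strand = character(0), position = integer(0),
      observed_base_plus = character(0), stringsAsFactors = FALSE
    )
  }

  truth_idx <- Filter(function(e) e[3] != config$background_rate,
                      config$effects)
  truth <- if (length(truth_idx)) {
    data.frame(
      chrom = sites$chrom[vapply(truth_idx, `[`, numeric(1), 1)],
      strand = sites$strand[vapply(truth_idx, `[`, numeric(1), 1)],
      position = sites$position[vapply(truth_idx, `[`, numeric(1), 1)],
      tissue = tissue_names[vapply(truth_idx, `[`, numeric(1), 2)],
      rate = vapply(truth_idx, `[`, numeric(1), 3),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(chrom = character(0), strand = character(0),
               position = integer(0), tissue = character(0),
               rate = numeric(0), stringsAsFactors = FALSE)
  }

  structure(list(sites = sites, libraries = libraries,
                 observations = observations, truth = truth,
                 config = config),
            class = "synthetic_dataset")
}

#' Generate a fully-null synthetic dataset
#'
#' As [generate_dataset()] with a uniform background editing rate everywhere
#' and an empty truth set; used to check false-discovery-rate control.
#'
#' @param config A [simulation_config()] with empty `effects`.
#' @return A `"synthetic_dataset"` whose `truth` has zero rows.
#' @export
generate_null_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  if (length(config$effects))
    stop("invalid field 'effects': must be empty for a null dataset")
  generate_dataset(config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic A-to-I editing dataset:",
      nrow(x$sites), "sites,", nrow(x$libraries), "libraries,",
      nrow(x$observations), "observations,",
      nrow(x$truth), "true tissue-specific pairs\n")
  invisible(x)
}

#' Write a synthetic dataset to the pipeline's input files
#'
#' Writes the three standard TSVs consumed by the readers ([read_sites()],
#' [read_libraries()], [read_observations()]) plus a truth table, so the
#' pipeline can be run end-to-end from files.
#'
#' @param dataset A `"synthetic_dataset"`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "synthetic_dataset"))
    stop("dataset must be a synthetic_dataset")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(sites = file.path(dir, "sites.tsv"),
             libraries = file.path(dir, "libraries.tsv"),
             observations = file.path(dir, "observations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(dataset$sites, paths["sites"])
  write_tsv(dataset$libraries, paths["libraries"])
  write_tsv(dataset$observations, paths["observations"])
  write_tsv(dataset$truth, paths["truth"])
  invisible(paths)
}
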