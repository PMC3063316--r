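#' Fisher's exact test p-value for a 2x2 table
#'
#' Computes the exact p-value for a 2x2 contingency table of edited/unedited
#' counts in one tissue (`a`, `b`) versus the pool of all other tissues
#' (`c`, `d`), with all margins fixed. Under the null hypothesis of equal
#' editing levels the tissue-side edited count follows a hypergeometric
#' distribution; the two-sided p-value sums the probabilities of all tables
#' with the same margins whose probability does not exceed that of the
#' observed table (probability-mass equality judged with a relative tolerance
#' of 1e-7), while the one-sided `"greater"` alternative sums the tail of
#' tables at least as enriched for edited counts in the tissue.
#'
#' @param a Edited count in the tissue of interest.
#' @param b Unedited count in the tissue of interest.
#' @param c Edited count pooled over all other tissues.
#' @param d Unedited count pooled over all other tissues.
#' @param alternative `"two.sided"` (default) or `"greater"`
#'   (editing enriched in the tissue).
#' @return A single p-value in (0, 1].
#' @examples
#' fisher_exact_p(3, 1, 1, 3)
#' fisher_exact_p(30, 10, 5, 95, alternative = "greater")
#' @seealso [detect_tissue_specificity()], [bh_procedure()]
#' @export
fisher_exact_p <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (length(a) != 1L || length(b) != 1L || length(c) != 1L || length(d) != 1L)
    stop("counts must be scalars")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers; got (",
         paste(counts, collapse = ", "), ")")
  n <- a + b + c + d
  if (n < 1) stop("at least one observation is required (a+b+c+d >= 1)")

  # x = edited count in the tissue; draw of size a+b from a+c edited
  # and b+d unedited sequences.
  m1 <- a + c   # edited margin
  m2 <- b + d   # unedited margin
  k  <- a + b   # tissue margin
  support <- max(0L, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[match(a, support)]

  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater   = sum(probs[support >= a])
  )
  min(1, p)
}

#' Benjamini-Hochberg step-up FDR procedure
#'
#' Ranks the p-values in ascending order, finds the largest rank `k` with
#' p(k) <= (k/m) q, and rejects the hypotheses of ranks 1..k. Adjusted
#' p-values use the standard min-over-larger-ranks (step-up) construction,
#' so a hypothesis is rejected exactly when its adjusted p-value is <= q.
#' Ties are stable: equal p-values receive equal adjusted values regardless
#' of input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param q Target false discovery rate, in (0, 1). Default 0.05.
#' @return An object of class `"bh_run"`: a list with components
#'   `m` (number of tests), `q`, `ranked_p` (ascending p-values),
#'   `k` (largest rank passing the step-up condition), `adjusted_p`
#'   (in input order), and `rejected` (logical, input order).
#' @examples
#' bh_procedure(c(0.01, 0.02, 0.04), q = 0.05)
#' @export
bh_procedure <- function(p, q = 0.05) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("q must be a single value in (0, 1)")
  if (length(p) == 0L)
    return(structure(list(m = 0L, q = q, ranked_p = numeric(0), k = 0L,
                          adjusted_p = numeric(0), rejected = logical(0)),
                     class = "bh_run"))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("all p-values must lie in [0, 1]")

  m <- length(p)
  ord <- order(p)                       # ties keep input order; result tie-stable
  ps <- p[ord]
  crit <- ps <= seq_len(m) / m * q
  k <- if (any(crit)) max(which(crit)) else 0L

  adj_sorted <- rev(cummin(rev(pmin(1, m * ps / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  rejected <- logical(m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE

  structure(list(m = m, q = q, ranked_p = ps, k = as.integer(k),
                 adjusted_p = adjusted, rejected = rejected),
            class = "bh_run")
}

#' @export
print.bh_run <- function(x, ...) {
  cat("Benjamini-Hochberg step-up run: m =", x$m, ", q =", x$q,
      ", k =", x$k, "(", sum(x$rejected), "rejected )\n")
  invisible(x)
}

#' Detect tissue-specific editing sites
#'
#' The core screen. For every tissue T and every site with at least one
#' retained observation in T (and at least `min_edited_in_tissue` edited
#' sequences there), a 2x2 table of edited/unedited counts in T versus the
#' pool of all other tissues is tested with [fisher_exact_p()]. Within each
#' tissue the [bh_procedure()] is applied to its own family of tests
#' (m = number of testable sites in that tissue), and the rejected
#' (site, tissue) pairs are reported as tissue-specific calls.
#'
#' @param counts A per-(site, tissue) count table as produced by
#'   [tabulate_observations()]: a data frame with columns `chrom`, `strand`,
#'   `position`, `tissue`, `edited`, `unedited` (and optionally `gene`).
#' @param q False discovery rate level per tissue. Default 0.05.
#' @param alternative Sidedness passed to [fisher_exact_p()].
#' @param min_edited_in_tissue Minimum edited count in the tissue for a
#'   (site, tissue) pair to be tested. Default 1: at least one edited
#'   sequence must have been observed in the tissue itself.
#' @return An object of class `"editing_specificity"`, a list with
#'   `calls` (data frame of rejected pairs: site columns, `tissue`, the four
#'   counts `a`,`b`,`c`,`d`, `p`, `adjusted_p`), `tests` (all tested pairs
#'   with raw and adjusted p-values and rejection flags), `m_per_tissue`
#'   (named integer vector), and the configuration used.
#' @examples
#' cfg <- simulation_config(n_tissues = 2, libraries_per_tissue = 1,
#'                          n_sites = 3, obs_per_site_per_library = 150,
#'                          background_rate = 0.02,
#'                          effects = list(c(1, 1, 0.5)), seed = 7)
#' ds <- generate_dataset(cfg)
#' cat <- curate_libraries(ds$libraries)
#' tab <- tabulate_observations(ds$observations, cat)
#' fit <- detect_tissue_specificity(tab)
#' summary(fit)
#' @export
detect_tissue_specificity <- function(counts, q = 0.05,
                                      alternative = c("two.sided", "greater"),
                                      min_edited_in_tissue = 1L) {
  alternative <- match.arg(alternative)
  needed <- c("chrom", "strand", "position", "tissue", "edited", "unedited")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols))
    stop("counts is missing columns: ", paste(missing_cols, collapse = ", "))

  has_gene <- "gene" %in% names(counts)
  empty_tests <- data.frame(chrom = character(0), strand = character(0),
                            position = integer(0), tissue = character(0),
                            a = integer(0), b = integer(0),
                            c = integer(0), d = integer(0),
                            p = numeric(0), adjusted_p = numeric(0),
                            rejected = logical(0),
                            stringsAsFactors = FALSE)

  tissues <- unique(counts$tissue)
  if (nrow(counts) == 0L || length(tissues) < 2L) {
    if (length(tissues) < 2L)
      warning("fewer than two tissues with observations: pool of other ",
              "tissues is empty, no tests performed")
    return(new_editing_specificity(empty_tests, counts, q, alternative,
                                   min_edited_in_tissue, has_gene))
  }

  site_key <- paste(counts$chrom, counts$strand, counts$position, sep = "\r")
  tot_edited   <- rowsum(counts$edited, site_key)
  tot_unedited <- rowsum(counts$unedited, site_key)
  idx <- match(site_key, rownames(tot_edited))

  a <- counts$edited
  b <- counts$unedited
  cc <- tot_edited[idx, 1L] - a
  dd <- tot_unedited[idx, 1L] - b

  testable <- (a + b) >= 1L & a >= min_edited_in_tissue
  tests <- counts[testable, c("chrom", "strand", "position", "tissue",
                              if (has_gene) "gene"), drop = FALSE]
  tests$a <- a[testable]; tests$b <- b[testable]
  tests$c <- cc[testable]; tests$d <- dd[testable]
  rownames(tests) <- NULL

  if (nrow(tests) == 0L)
    return(new_editing_specificity(empty_tests, counts, q, alternative,
                                   min_edited_in_tissue, has_gene))

  tests$p <- vapply(seq_len(nrow(tests)), function(i)
    fisher_exact_p(tests$a[i], tests$b[i], tests$c[i], tests$d[i],
                   alternative = alternative), numeric(1))

  tests$adjusted_p <- NA_real_
  tests$rejected <- FALSE
  for (tis in unique(tests$tissue)) {
    sel <- tests$tissue == tis
    run <- bh_procedure(tests$p[sel], q = q)
    tests$adjusted_p[sel] <- run$adjusted_p
    tests$rejected[sel] <- run$rejected
  }

  new_editing_specificity(tests, counts, q, alternative,
                          min_edited_in_tissue, has_gene)
}

new_editing_specificity <- function(tests, counts, q, alternative,
                                    min_edited_in_tissue, has_gene) {
  m_per_tissue <- if (nrow(tests)) {
    tab <- table(tests$tissue)
    stats::setNames(as.integer(tab), names(tab))
  } else stats::setNames(integer(0), character(0))
  calls <- tests[tests$rejected %in% TRUE, , drop = FALSE]
  calls$rejected <- NULL
  rownames(calls) <- NULL
  structure(list(calls = calls, tests = tests, m_per_tissue = m_per_tissue,
                 q = q, alternative = alternative,
                 min_edited_in_tissue = min_edited_in_tissue,
                 n_tissues = length(unique(counts$tissue)),
                 n_sites = length(unique(paste(counts$chrom, counts$strand,
                                               counts$position)))),
            class = "editing_specificity")
}

#' @export
print.editing_specificity <- function(x, ...) {
  cat("Tissue-specific A-to-I editing screen\n")
  cat("  sites x tissues tabulated:", x$n_sites, "x", x$n_tissues, "\n")
  cat("  tests:", nrow(x$tests), " (per-tissue BH at q =", x$q,
      ",", x$alternative, "Fisher)\n")
  cat("  tissue-specific calls:", nrow(x$calls), "\n")
  invisible(x)
}

#' @describeIn detect_tissue_specificity Summary with per-tissue test counts
#'   and the table of calls.
#' @param object,x An `editing_specificity` object.
#' @param ... Unused.
#' @export
summary.editing_specificity <- function(object, ...) {
  print(object)
  if (length(object$m_per_tissue)) {
    cat("\nTests per tissue (m):\n")
    print(object$m_per_tissue)
  }
  if (nrow(object$calls)) {
    cat("\nCalls:\n")
    print(object$calls, digits = 3)
  }
  invisible(object)
}

#' @describeIn detect_tissue_specificity Extract the calls as a data frame.
#' @param row.names,optional Passed through (unused).
#' @export
as.data.frame.editing_specificity <- function(x, row.names = NULL,
                                              optional = FALSE, ...) {
  x$calls
}

#' Editing level from chromatogram peak areas
#'
#' Estimates the editing level at a site as the percentage ratio of the 'G'
#' peak over the sum of the 'G' and 'A' peaks in a sequencing chromatogram,
#' rounded half-up to one decimal place.
#'
#' @param g_count 'G' peak area (non-negative).
#' @param total Sum of 'G' and 'A' peak areas (positive).
#' @return Percentage(s) in `[0, 100]` with one decimal place.
#' @examples
#' editing_level_percent(151, 855)  # 17.7
#' editing_level_percent(70, 888)   # 7.9
#' @export
editing_level_percent <- function(g_count, total) {
  if (any(!is.finite(g_count)) || any(g_count < 0))
    stop("g_count must be non-negative")
  if (any(!is.finite(total)) || any(total <= 0))
    stop("total must be positive")
  if (any(g_count > total))
    stop("g_count cannot exceed total")
  floor(1000 * g_count / total + 0.5) / 10
}
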