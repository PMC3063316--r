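test_that("Fisher p-values match hand-enumerable tables", {
  # degenerate: no edited sequences anywhere, only one table possible
  expect_equal(fisher_exact_p(0, 10, 0, 10), 1)
  # perfectly symmetric table
  expect_equal(fisher_exact_p(1, 1, 1, 1), 1)
  # margins (4,4,4,4): probs 1/70, 16/70, 36/70, 16/70, 1/70;
  # observed a=3 -> two-sided mass = (1+16+16+1)/70
  expect_equal(fisher_exact_p(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_p(3, 1, 1, 3, alternative = "greater"),
               17 / 70, tolerance = 1e-12)
  expect_error(fisher_exact_p(-1, 1, 1, 1), "non-negative")
})

test_that("Fisher p equals enumeration oracle and fisher.test on random tables", {
  set.seed(42)
  for (i in 1:200) {
    t4 <- as.integer(rmultinom(1, sample(1:60, 1), rep(0.25, 4)))
    p <- fisher_exact_p(t4[1], t4[2], t4[3], t4[4])
    expect_equal(p, oracle_fisher_p(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(t4, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
    pg <- fisher_exact_p(t4[1], t4[2], t4[3], t4[4], alternative = "greater")
    expect_equal(pg, oracle_fisher_p(t4[1], t4[2], t4[3], t4[4], "greater"),
                 tolerance = 1e-10)
  }
})

test_that("two-sided Fisher p is invariant to swapping tissue and pool", {
  set.seed(7)
  for (i in 1:50) {
    t4 <- as.integer(rmultinom(1, sample(2:40, 1), rep(0.25, 4)))
    expect_equal(fisher_exact_p(t4[1], t4[2], t4[3], t4[4]),
                 fisher_exact_p(t4[3], t4[4], t4[1], t4[2]),
                 tolerance = 1e-12)
  }
})

test_that("BH step-up matches its definition on worked examples", {
  r1 <- bh_procedure(0.5, q = 0.05)
  expect_equal(r1$k, 0L)
  expect_equal(r1$adjusted_p, 0.5)
  expect_false(any(r1$rejected))

  expect_false(any(bh_procedure(c(1, 1, 1), q = 0.05)$rejected))

  r3 <- bh_procedure(c(0.01, 0.02, 0.04), q = 0.05)
  expect_equal(r3$k, 3L)                      # 0.04 <= (3/3) * 0.05
  expect_true(all(r3$rejected))
  expect_equal(r3$adjusted_p, c(0.03, 0.03, 0.04))
  expect_equal(r3$ranked_p, c(0.01, 0.02, 0.04))

  expect_error(bh_procedure(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with the step-up oracle and p.adjust on random vectors", {
  set.seed(11)
  for (i in 1:100) {
    m <- sample(1:40, 1)
    p <- round(runif(m), 3)   # rounding forces ties
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    run <- bh_procedure(p, q)
    orc <- oracle_bh(p, q)
    expect_equal(run$k, as.integer(orc$k))
    expect_equal(run$rejected, orc$rejected)
    expect_equal(run$adjusted_p, orc$adjusted, tolerance = 1e-12)
    expect_equal(run$adjusted_p, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # adjusted values dominate raw values; rejection <=> adjusted <= q
    expect_true(all(run$adjusted_p >= p - 1e-12))
    expect_equal(run$rejected, run$adjusted_p <= q)
  }
})

test_that("BH rejections are monotone in q and invariant to input order", {
  set.seed(13)
  p <- runif(25)
  perm <- sample(25)
  r_perm <- bh_procedure(p[perm], 0.1)
  r_orig <- bh_procedure(p, 0.1)
  expect_equal(r_perm$adjusted_p, r_orig$adjusted_p[perm])
  for (i in 1:20) {
    q1 <- runif(1, 0.01, 0.5); q2 <- runif(1, q1, 0.6)
    rej1 <- which(bh_procedure(p, q1)$rejected)
    rej2 <- which(bh_procedure(p, q2)$rejected)
    expect_true(all(rej1 %in% rej2))
  }
})

test_that("a strong single-tissue enrichment is the only call made", {
  # one site, 200 obs at 0.5 in tissue A vs 1000 obs at 0.01 spread over
  # five other tissues
  cfg <- simulation_config(6, 1, 1, 200, 0.01,
                           effects = list(c(1, 1, 0.5)), seed = 301)
  ds <- generate_dataset(cfg)
  cat <- curate_libraries(ds$libraries)
  tab <- suppressMessages(tabulate_observations(ds$observations, cat))
  fit <- detect_tissue_specificity(tab, alternative = "greater")
  expect_equal(nrow(fit$calls), 1L)
  expect_equal(fit$calls$tissue, "tissue01")
  expect_equal(fit$calls$position, ds$truth$position)
  expect_lte(fit$calls$adjusted_p, 0.05)
})

test_that("a single tissue yields zero tests and a warning", {
  cfg <- simulation_config(1, 2, 3, 20, 0.2, seed = 6)
  ds <- generate_dataset(cfg)
  cat <- curate_libraries(ds$libraries)
  tab <- suppressMessages(tabulate_observations(ds$observations, cat))
  expect_warning(fit <- detect_tissue_specificity(tab), "fewer than two")
  expect_equal(nrow(fit$tests), 0L)
  expect_equal(nrow(fit$calls), 0L)
})

test_that("min_edited_in_tissue gates which pairs are tested", {
  counts <- data.frame(
    chrom = "chr1", strand = "+", position = 10L,
    tissue = c("a", "b"), edited = c(0L, 5L), unedited = c(20L, 15L),
    stringsAsFactors = FALSE)
  fit <- detect_tissue_specificity(counts)
  expect_equal(fit$tests$tissue, "b")   # tissue a has no edited sequence
  fit0 <- detect_tissue_specificity(counts, min_edited_in_tissue = 0L)
  expect_setequal(fit0$tests$tissue, c("a", "b"))
})

test_that("per-tissue false discovery proportion is controlled on nulls", {
  # fully-null pipeline runs; BH bounds the per-tissue family FDR at q
  nrep <- 300
  fdp <- numeric(0)
  for (r in seq_len(nrep)) {
    cfg <- simulation_config(5, 1, 20, 100, 0.1, seed = 40000 + r)
    ds <- generate_null_dataset(cfg)
    cat <- curate_libraries(ds$libraries)
    tab <- suppressMessages(tabulate_observations(ds$observations, cat))
    fit <- detect_tissue_specificity(tab)
    # under the global null FDP per tissue family is 1{any rejection}
    fdp <- c(fdp, vapply(split(fit$tests$rejected, fit$tests$tissue),
                         any, logical(1)))
  }
  mc_se <- stats::sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 3 * mc_se)
})

test_that("editing level percentages are exact half-up one-decimal ratios", {
  expect_equal(editing_level_percent(0, 100), 0)
  expect_equal(editing_level_percent(100, 100), 100)
  expect_equal(editing_level_percent(1, 16), 6.3)   # 6.25 rounds up
  expect_equal(editing_level_percent(c(151, 70), c(855, 888)), c(17.7, 7.9))
  expect_error(editing_level_percent(5, 0), "positive")
  expect_error(editing_level_percent(10, 5), "exceed")
  expect_error(editing_level_percent(-1, 5), "non-negative")
})
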