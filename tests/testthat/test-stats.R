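make_profile <- function(counts, flags = NULL) {
  uid <- rep(sprintf("u%02d", seq_along(counts)), counts)
  n <- length(uid)
  hits <- tibble::tibble(
    chain_id = paste0(uid, "_H"), unit_id = uid, chain_type = "H",
    motif_tag = "DeAmdH", imgt_start = "57", rule_kind = "motif_scan",
    positions = replicate(n, c("57", "58"), simplify = FALSE),
    germline = FALSE, therapeutic = FALSE, surface = NA_character_)
  if (!is.null(flags)) for (f in names(flags)) hits[[f]] <- flags[[f]]
  structure(list(hits = hits,
                 units = tibble::tibble(
                   unit_id = sprintf("u%02d", seq_along(counts))),
                 flags_applied = c("germline", "therapeutic")),
            class = "liab_profile")
}

test_that("dataset summary computes prevalence and per-unit statistics", {
  prof <- make_profile(c(2, 0, 3, 1))
  s <- summarize_dataset(prof)
  o <- s$overview
  expect_equal(o$n_units, 4L)
  expect_equal(o$pct_with_liability, 75)
  expect_equal(o$total_liabilities, 6L)
  expect_equal(o$mean_per_unit, 1.5)
  expect_equal(o$median_per_unit, 1.5)
  none <- s$combos[s$combos$combo == "none", ]
  expect_equal(none$remaining_liabilities, o$total_liabilities)
  expect_equal(none$remaining_units, 3)
  expect_error(summarize_dataset(list(hits = prof$hits,
                                      units = prof$units[0, ])),
               "empty")
})

test_that("an exactly 40%-flagged dataset leaves exactly 60% remaining", {
  prof <- synthetic_profiles(60, seed = 91, germline_rate = 0.4)
  total <- prof$rates$total
  s <- summarize_dataset(prof, combos = list(g = "germline"))
  expect_equal(s$combos$benign_liabilities, prof$rates$germline)
  expect_equal(s$combos$remaining_liabilities, total - prof$rates$germline)
  expect_equal(s$combos$pct_liabilities_remaining,
               100 * (total - prof$rates$germline) / total)
})

test_that("flag combinations are monotone and conserve totals", {
  combos <- list(none = character(0), g = "germline", t = "therapeutic",
                 s = "surface", gt = c("germline", "therapeutic"),
                 all = c("germline", "therapeutic", "surface"))
  for (seed in 1:25) {
    prof <- synthetic_profiles(
      30, seed = seed,
      germline_rate = runif(1, 0.1, 0.6),
      therapeutic_rate = runif(1, 0.1, 0.6),
      buried_rate = runif(1, 0, 0.5))
    s <- summarize_dataset(prof, combos = combos)$combos
    total <- nrow(prof$hits)
    expect_equal(s$benign_liabilities + s$remaining_liabilities,
                 rep(total, nrow(s)))
    rem <- stats::setNames(s$remaining_liabilities, s$combo)
    remu <- stats::setNames(s$remaining_units, s$combo)
    for (single in c("g", "t", "s")) {
      expect_lte(rem[["all"]], rem[[single]])
      expect_lte(remu[["all"]], remu[[single]])
      expect_lte(rem[[single]], rem[["none"]])
      expect_lte(remu[[single]], remu[["none"]])
    }
    expect_lte(rem[["gt"]], min(rem[["g"]], rem[["t"]]))
  }
})

test_that("summaries are invariant under profile order permutation", {
  prof <- synthetic_profiles(20, seed = 92)
  perm <- prof
  withr::with_seed(9, idx <- sample(nrow(prof$hits)))
  perm$hits <- perm$hits[idx, ]
  perm$units <- perm$units[sample(nrow(perm$units)), ]
  s1 <- summarize_dataset(prof)
  s2 <- summarize_dataset(perm)
  expect_equal(s2$overview, s1$overview)
  expect_equal(s2$combos, s1$combos)
})

test_that("region distribution keys boundary hits by flanking regions", {
  hits <- tibble::tibble(
    positions = list(c("57", "58"), c("38", "39"), c("20", "21"),
                     character(0)))
  d <- region_distribution(hits)
  expect_equal(d$n[d$region == "CDR2"], 1L)
  expect_equal(d$n[d$region == "CDR1-FR2"], 1L)
  expect_equal(d$n[d$region == "FR1"], 1L)
  expect_equal(d$n[d$region == "fv"], 1L)
})

test_that("Fisher's exact test matches enumeration and the reference", {
  tabs <- list(
    germline = matrix(c(5, 4, 26, 17), 2),
    surface = matrix(c(10, 17, 21, 4), 2),
    therapeutic = matrix(c(5, 10, 26, 11), 2),
    all_flags = matrix(c(12, 19, 19, 2), 2),
    unit = matrix(c(1, 1, 1, 1), 2))
  for (nm in names(tabs)) {
    res <- fisher_exact_2x2(tabs[[nm]])
    expect_equal(res$p_value, oracle_fisher_p(tabs[[nm]]), label = nm)
    expect_equal(res$p_value,
                 stats::fisher.test(tabs[[nm]])$p.value,
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  # random small tables against full enumeration
  withr::with_seed(93, {
    for (k in 1:40) {
      tab <- matrix(rpois(4, 6), 2)
      if (sum(tab) == 0) next
      expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab))
    }
  })
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 1, 4), 2))$odds_ratio, Inf)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
})

test_that("Welch t-test handles degenerate and closed-form cases", {
  expect_equal(welch_t_p(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_lt(welch_t_p(c(0, 0.01, 0), c(100, 99.99, 100)), 1e-3)
  a <- c(1.1, 2.3, 3.1, 4.8)
  b <- c(2.0, 2.2, 4.4)
  # closed-form Welch statistic
  se <- sqrt(var(a) / length(a) + var(b) / length(b))
  t_stat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / length(a))^2 / (length(a) - 1) +
                  (var(b) / length(b))^2 / (length(b) - 1))
  p_manual <- 2 * stats::pt(-abs(t_stat), df)
  expect_equal(welch_t_p(a, b), p_manual, tolerance = 1e-12)
})

test_that("pairwise chi-squared with Bonferroni scales by the pair count", {
  x <- c(rep(0, 20), rep(1, 15), rep(2, 10), rep(3, 5))
  res <- chi2_pairwise_bonferroni(list(a = x, b = x, c = x))
  expect_equal(nrow(res), 3L)
  expect_equal(res$p_adj, rep(1, 3))
  y <- c(rep(0, 5), rep(1, 10), rep(2, 15), rep(3, 20))
  res2 <- chi2_pairwise_bonferroni(list(a = x, b = y, c = x))
  expect_equal(res2$p_adj, pmin(1, res2$p_raw * 3))
  m <- chi2_pairwise_bonferroni(list(a = x, b = y))
  raw <- suppressWarnings(stats::chisq.test(rbind(
    tabulate(x + 1, 4), tabulate(y + 1, 4)))$p.value)
  expect_equal(m$p_raw, raw)
})

test_that("benchmark stratification shows the planted effect direction", {
  bench <- generate_benchmark_records(40, seed = 94)
  res <- benchmark_flags(bench$records, bench$profile,
                         combos = list(gt = c("germline", "therapeutic")),
                         exclude_training = TRUE)
  strat <- res$stratified
  fl <- strat[strat$flagged, ]
  un <- strat[!strat$flagged, ]
  m <- merge(fl, un, by = "condition")
  expect_true(all(m$median.x < m$median.y))
  ox <- res$oxidation
  expect_true(all(c("ox_flag", "p_value") %in% names(ox)))
  # planted direction: flagged methionines sit in non-oxidising molecules
  expect_lt(ox$odds_ratio, 1)
})

test_that("benchmarking with every record in training warns and is empty", {
  bench <- generate_benchmark_records(10, seed = 95,
                                      training_fraction = 1)
  expect_warning(
    res <- benchmark_flags(bench$records, bench$profile,
                           exclude_training = TRUE),
    "no benchmark records")
  expect_equal(nrow(res$stratified), 0L)
})
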