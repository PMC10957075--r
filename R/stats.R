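.default_combos <- function(surface = FALSE) {
  combos <- list(none = character(0), germline = "germline",
                 therapeutic = "therapeutic",
                 `germline+therapeutic` = c("germline", "therapeutic"))
  if (surface) {
    combos$surface <- "surface"
    combos$all <- c("germline", "therapeutic", "surface")
  } else {
    combos$all <- c("germline", "therapeutic")
  }
  combos
}

#' Summarize liability prevalence and flag reduction over a dataset
#'
#' Computes per-dataset survey quantities (share of units with at least one
#' liability, totals, mean/sd/median per unit, per-type and per-region
#' counts) and, for each flag combination, the remaining (non-benign)
#' liabilities and the remaining units (units with at least one non-benign
#' liability). A liability is removed by a combination when it is benign
#' under it; paired heavy+light units count as one molecule.
#'
#' @param profile A `liab_profile` from [profile_antibody()], or a list
#'   with `hits` and `units` tibbles.
#' @param combos Named list of flag combinations (character vectors among
#'   germline/therapeutic/surface). Defaults to none, each sequence flag,
#'   their combination, and all (incl. surface when it was applied).
#' @param config A [flag_config()].
#' @param group_by Optional unit metadata column to stratify the per-unit
#'   statistics by (e.g. `"species_label"`).
#' @return An object of class `liab_summary` with components `overview`
#'   (one-row tibble), `per_type`, `per_region`, `combos` (one row per
#'   combination), and optionally `groups`.
#' @export
summarize_dataset <- function(profile, combos = NULL,
                              config = flag_config(), group_by = NULL) {
  hits <- profile$hits
  units <- profile$units
  if (is.null(units) || !nrow(units)) abort("empty profile: no units")
  if (is.null(combos)) {
    combos <- .default_combos("surface" %in% (profile$flags_applied %||%
                                                character(0)))
  }
  if (!"unit_id" %in% names(hits)) hits$unit_id <- hits$chain_id

  per_unit <- tibble(unit_id = units$unit_id) |>
    dplyr::left_join(dplyr::count(hits, .data$unit_id), by = "unit_id") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  overview <- tibble(
    n_units = nrow(units),
    pct_with_liability = 100 * mean(per_unit$n > 0),
    total_liabilities = sum(per_unit$n),
    mean_per_unit = mean(per_unit$n),
    sd_per_unit = stats::sd(per_unit$n),
    median_per_unit = stats::median(per_unit$n)
  )
  per_type <- if ("severity" %in% names(hits)) {
    dplyr::count(hits, .data$motif_tag, .data$severity, name = "n")
  } else {
    dplyr::count(hits, .data$motif_tag, name = "n")
  }
  per_region <- if ("positions" %in% names(hits)) {
    region_distribution(hits)
  } else {
    tibble(region = character(0), n = integer(0))
  }

  combo_rows <- purrr::imap(combos, function(combo, label) {
    flags_str <- paste(combo, collapse = "+")
    benign <- benign_under(hits, combo, config)
    rem <- hits[!benign, , drop = FALSE]
    rem_units <- tibble(unit_id = units$unit_id) |>
      dplyr::left_join(dplyr::count(rem, .data$unit_id), by = "unit_id") |>
      dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
    tibble(
      combo = label,
      flags = flags_str,
      benign_liabilities = sum(benign),
      remaining_liabilities = sum(!benign),
      remaining_units = sum(rem_units$n > 0),
      pct_liabilities_remaining = 100 * sum(!benign) / max(1L, nrow(hits)),
      pct_units_remaining = 100 * mean(rem_units$n > 0),
      median_remaining_per_unit = stats::median(rem_units$n)
    )
  })
  out <- list(overview = overview, per_type = per_type,
              per_region = per_region,
              combos = dplyr::bind_rows(combo_rows))
  if (!is.null(group_by)) {
    grp <- units[[group_by]]
    out$groups <- tibble(unit_id = units$unit_id, group = grp) |>
      dplyr::left_join(per_unit, by = "unit_id") |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n_units = dplyr::n(), mean_per_unit = mean(.data$n),
                       sd_per_unit = stats::sd(.data$n),
                       median_per_unit = stats::median(.data$n),
                       .groups = "drop")
  }
  structure(out, class = "liab_summary")
}

#' @export
print.liab_summary <- function(x, ...) {
  o <- x$overview
  cat("<liab_summary> ", o$n_units, " unit(s); ",
      sprintf("%.1f%%", o$pct_with_liability), " with >=1 liability; ",
      o$total_liabilities, " liabilities (mean ",
      sprintf("%.2f", o$mean_per_unit), "/unit)\n", sep = "")
  print(x$combos[, c("combo", "remaining_liabilities",
                     "pct_liabilities_remaining", "remaining_units")])
  invisible(x)
}

#' Per-region liability counts
#'
#' Counts liabilities per IMGT region; motifs straddling a CDR and its
#' flanking framework are counted in boundary bins keyed by the two
#' regions (e.g. `"CDR1-FR2"`).
#'
#' @param hits A hits tibble.
#' @return Tibble with `region` and `n`.
#' @export
region_distribution <- function(hits) {
  if (!nrow(hits)) return(tibble(region = character(0), n = integer(0)))
  key <- vapply(hits$positions, function(pos) {
    if (!length(pos)) return("fv")
    regs <- imgt_region(pos)
    u <- unique(regs)
    if (length(u) == 1L) u else paste(u, collapse = "-")
  }, character(1))
  dplyr::count(tibble(region = key), .data$region, name = "n")
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. The odds ratio is the
#' sample odds ratio `a*d / (b*c)` (with `Inf`/`0` conventions when a
#' denominator or numerator vanishes).
#'
#' @param table A 2x2 matrix of non-negative integer counts (rows:
#'   outcome, cols: flag status).
#' @return One-row tibble: `p_value`, `odds_ratio`.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(5, 4, 26, 17), 2))
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table))) {
    abort("fisher_exact_2x2() needs a 2x2 matrix of non-negative integers")
  }
  if (sum(table) == 0) abort("all-zero table")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  m <- a + b          # row-1 margin
  k <- a + c_         # col-1 margin
  n_tot <- sum(table)
  lo <- max(0L, k - (n_tot - m))
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n_tot - m, k)
  p_obs <- stats::dhyper(a, m, n_tot - m, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    a * d / (b * c_)
  }
  tibble(p_value = min(1, p), odds_ratio = or)
}

#' Welch two-sample t-test p-value
#'
#' Two-sided Welch test; the degenerate case of two zero-variance
#' identical samples returns p = 1 by convention.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return Two-sided p-value.
#' @export
welch_t_p <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) abort("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (a[1] == b[1]) 1 else 0)
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Pairwise chi-squared tests with Bonferroni correction
#'
#' Compares per-sequence liability-count distributions between every pair
#' of datasets with a chi-squared test on the two histograms; adjusted
#' p-values are `min(1, p * m)` with `m` the number of pairs. Count bins
#' whose expected value falls below 1 are pooled into the preceding bin
#' (noted in the output).
#'
#' @param counts Named list of integer vectors (per-sequence liability
#'   counts, one vector per dataset).
#' @return Tibble: `dataset1`, `dataset2`, `p_raw`, `p_adj`, `pooled`.
#' @export
chi2_pairwise_bonferroni <- function(counts) {
  if (length(counts) < 2L) abort("need >= 2 datasets")
  nm <- names(counts) %||% paste0("d", seq_along(counts))
  pairs <- utils::combn(seq_along(counts), 2L)
  m <- ncol(pairs)
  rows <- purrr::map(seq_len(m), function(i) {
    i1 <- pairs[1, i]; i2 <- pairs[2, i]
    mx <- max(counts[[i1]], counts[[i2]])
    h1 <- tabulate(counts[[i1]] + 1L, nbins = mx + 1L)
    h2 <- tabulate(counts[[i2]] + 1L, nbins = mx + 1L)
    tab <- rbind(h1, h2)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    pooled <- FALSE
    repeat {
      exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      bad <- which(apply(exp_tab, 2, min) < 1)
      bad <- bad[bad > 1L]
      if (!length(bad) || ncol(tab) <= 2L) break
      j <- bad[length(bad)]
      tab[, j - 1L] <- tab[, j - 1L] + tab[, j]
      tab <- tab[, -j, drop = FALSE]
      pooled <- TRUE
    }
    p <- if (identical(tab[1, ], tab[2, ])) 1 else
      suppressWarnings(stats::chisq.test(tab)$p.value)
    tibble(dataset1 = nm[i1], dataset2 = nm[i2], p_raw = p,
           p_adj = min(1, p * m), pooled = pooled)
  })
  dplyr::bind_rows(rows)
}

#' Benchmark flags against measured chemical modifications
#'
#' Joins measured modification records to profiled liabilities by
#' (therapeutic unit, motif tag, IMGT start) and, per flag combination,
#' stratifies the measured percent modification by flag status (benign vs
#' not). For the oxidation condition, builds a 2x2 contingency table
#' (oxidation x flagged) over therapeutics with at least one annotated
#' methionine — a molecule counts as flagged when at least one of its
#' methionine liabilities is benign under the combination — and runs
#' [fisher_exact_2x2()] on it. Therapeutics in the flag's training set can
#' be excluded.
#'
#' @param records Tibble: `therapeutic_id`, `motif_tag`, `imgt_start`,
#'   `condition` (one of deamidation_high_pH, deamidation_low_pH,
#'   isomerization_low_pH, oxidation), `value` (percent modification; for
#'   oxidation, 1/0), `in_flag_training` (logical).
#' @param profile A `liab_profile` whose `unit_id`s are the therapeutic
#'   ids.
#' @param combos Named list of flag combinations.
#' @param exclude_training Drop records with `in_flag_training = TRUE`.
#' @param config A [flag_config()].
#' @return List with `stratified` (per combo x condition, the flagged and
#'   unflagged `value` distributions with medians), `oxidation` (per
#'   combo, the 2x2 cells and Fisher p), and `unmatched` (records that
#'   joined to no profiled liability).
#' @export
benchmark_flags <- function(records, profile, combos = NULL,
                            exclude_training = TRUE,
                            config = flag_config()) {
  if (is.null(combos)) combos <- .default_combos(FALSE)
  hits <- profile$hits
  if (!"unit_id" %in% names(hits)) hits$unit_id <- hits$chain_id
  if (exclude_training) {
    records <- records[!records$in_flag_training, , drop = FALSE]
  }
  if (!nrow(records)) {
    warn("no benchmark records remain after training-set exclusion")
    return(list(stratified = tibble(), oxidation = tibble(),
                unmatched = records))
  }
  hkey <- paste(hits$unit_id, hits$motif_tag, hits$imgt_start, sep = "\r")
  rkey <- paste(records$therapeutic_id, records$motif_tag,
                records$imgt_start, sep = "\r")
  idx <- match(rkey, hkey)
  unmatched <- records[is.na(idx), , drop = FALSE]
  records <- records[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  strat <- purrr::imap(combos, function(combo, label) {
    benign <- benign_under(hits[idx, , drop = FALSE], combo, config)
    pct <- records$condition != "oxidation"
    if (!any(pct)) return(NULL)
    tibble(combo = label, condition = records$condition[pct],
           value = records$value[pct],
           flagged = benign[pct]) |>
      dplyr::group_by(.data$combo, .data$condition, .data$flagged) |>
      dplyr::summarise(n = dplyr::n(), median = stats::median(.data$value),
                       mean = mean(.data$value),
                       values = list(.data$value), .groups = "drop")
  })

  ox <- purrr::imap(combos, function(combo, label) {
    sel <- records$condition == "oxidation"
    if (!any(sel)) return(NULL)
    benign <- benign_under(hits[idx, , drop = FALSE], combo, config)
    per_mol <- tibble(id = records$therapeutic_id[sel],
                      oxidized = records$value[sel] > 0,
                      flagged = benign[sel]) |>
      dplyr::group_by(.data$id) |>
      dplyr::summarise(oxidized = any(.data$oxidized),
                       flagged = any(.data$flagged), .groups = "drop")
    tab <- matrix(c(
      sum(per_mol$oxidized & per_mol$flagged),
      sum(!per_mol$oxidized & per_mol$flagged),
      sum(per_mol$oxidized & !per_mol$flagged),
      sum(!per_mol$oxidized & !per_mol$flagged)), 2)
    ft <- fisher_exact_2x2(tab)
    tibble(combo = label,
           ox_flag = tab[1, 1], ox_noflag = tab[1, 2],
           noox_flag = tab[2, 1], noox_noflag = tab[2, 2],
           p_value = ft$p_value, odds_ratio = ft$odds_ratio)
  })
  list(stratified = dplyr::bind_rows(purrr::compact(strat)),
       oxidation = dplyr::bind_rows(purrr::compact(ox)),
       unmatched = unmatched)
}
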