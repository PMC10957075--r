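#' Quality-control filter for antibody sequences and numbered chains
#'
#' Applies, in order: length within \[40, 1000\]; standard residues only; no
#' `!` character; numbering/germline assignment present (`v_call` and
#' `j_call`); all three CDRs non-empty; for paired input, each unit has
#' exactly one heavy and one light chain; deduplication on the exact
#' variable-domain string (paired: concatenated heavy+light). Each rejected
#' record gets exactly one reason: the first failing rule. Rejections are
#' data, not errors, and the filter is idempotent.
#'
#' @param x Either a chain tibble (as from [read_numbered_chains()]) or a
#'   raw-sequence tibble with columns `id` and `sequence` (for which only
#'   the length/residue/`!`/duplicate rules apply).
#' @param paired If `TRUE`, enforce the pairing rule per `unit_id` and
#'   deduplicate on the concatenated H+L string.
#' @return `list(kept = <same shape as x>, ledger = tibble(id, reason))`.
#' @export
#' @examples
#' raw <- tibble::tibble(id = c("a", "b"),
#'                       sequence = c(strrep("A", 50), strrep("A", 20)))
#' qc_filter(raw)$ledger
qc_filter <- function(x, paired = FALSE) {
  if ("sequence" %in% names(x)) {
    qc_filter_raw(x)
  } else {
    qc_filter_chains(x, paired = paired)
  }
}

qc_filter_raw <- function(seqs) {
  reason <- rep(NA_character_, nrow(seqs))
  len <- nchar(seqs$sequence)
  reason[is.na(reason) & (len < 40L | len > 1000L)] <- "length"
  has_bang <- grepl("!", seqs$sequence, fixed = TRUE)
  clean <- gsub("!", "", seqs$sequence, fixed = TRUE)
  nonstd <- grepl(paste0("[^", paste(aa_standard, collapse = ""), "]"), clean)
  reason[is.na(reason) & nonstd] <- "residue"
  reason[is.na(reason) & has_bang] <- "exclamation"
  ok <- is.na(reason)
  dup <- ok & duplicated(ifelse(ok, seqs$sequence, NA))
  reason[dup] <- "duplicate"
  list(kept = seqs[is.na(reason), , drop = FALSE],
       ledger = tibble(id = seqs$id[!is.na(reason)],
                       reason = reason[!is.na(reason)]))
}

qc_filter_chains <- function(chains, paired = FALSE) {
  if (!nrow(chains)) {
    return(list(kept = chains, ledger = tibble(id = character(0),
                                               reason = character(0))))
  }
  per <- chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      unit_id = dplyr::first(.data$unit_id),
      chain_type = dplyr::first(.data$chain_type),
      sequence = paste0(.data$residue, collapse = ""),
      n = dplyr::n(),
      std = all(.data$residue %in% aa_standard),
      bang = any(.data$residue == "!"),
      has_calls = !is.na(dplyr::first(.data$v_call)) &&
        !is.na(dplyr::first(.data$j_call)),
      cdr1 = any(.data$position >= 27L & .data$position <= 38L),
      cdr2 = any(.data$position >= 56L & .data$position <= 65L),
      cdr3 = any(.data$position >= 105L & .data$position <= 117L),
      .groups = "drop"
    )
  # preserve input chain order
  per <- per[match(unique(chains$chain_id), per$chain_id), ]
  reason <- rep(NA_character_, nrow(per))
  reason[is.na(reason) & (per$n < 40L | per$n > 1000L)] <- "length"
  reason[is.na(reason) & !per$std] <- "residue"
  reason[is.na(reason) & per$bang] <- "exclamation"
  reason[is.na(reason) & !per$has_calls] <- "germline"
  reason[is.na(reason) & !(per$cdr1 & per$cdr2 & per$cdr3)] <- "cdr_missing"

  if (paired) {
    key <- per$unit_id
    for (u in unique(key)) {
      idx <- which(key == u & is.na(reason))
      if (!length(idx)) next
      types <- per$chain_type[idx]
      ok_pair <- length(idx) == 2L && sum(types == "H") == 1L &&
        sum(types %in% c("K", "L")) == 1L
      if (!ok_pair) reason[idx] <- "pairing"
    }
    # dedupe on concatenated H+L of surviving units
    idx_ok <- which(is.na(reason))
    seen <- character(0)
    for (u in unique(per$unit_id[idx_ok])) {
      idx <- idx_ok[per$unit_id[idx_ok] == u]
      idx <- idx[order(per$chain_type[idx] != "H")] # H first
      cat_seq <- paste0(per$sequence[idx], collapse = "")
      if (cat_seq %in% seen) reason[idx] <- "duplicate" else
        seen <- c(seen, cat_seq)
    }
  } else {
    ok <- is.na(reason)
    dup <- ok & duplicated(ifelse(ok, per$sequence, NA))
    reason[dup] <- "duplicate"
  }

  kept_ids <- per$chain_id[is.na(reason)]
  list(kept = chains[chains$chain_id %in% kept_ids, , drop = FALSE],
       ledger = tibble(id = per$chain_id[!is.na(reason)],
                       reason = reason[!is.na(reason)]))
}
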