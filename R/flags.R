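#' Flag configuration
#'
#' Houses the thresholds and modes of the three low-risk flags.
#'
#' @param therapeutic_threshold Fraction of marketed-panel chains above
#'   which a (motif, IMGT start) is flagged; strict `>`. Default 0.05.
#' @param exposure_threshold Relative SASA above which a residue is
#'   exposed; strict `>`. Default 0.075.
#' @param germline_mode `"assigned"` consults the chain's assigned top V
#'   and J segments; `"any"` consults every human segment in the reference.
#' @param partial_policy Whether a `partial` surface class counts as
#'   benign; default `"not_benign"` (conservative).
#' @return A list of class `flag_config`.
#' @export
flag_config <- function(therapeutic_threshold = 0.05,
                        exposure_threshold = 0.075,
                        germline_mode = c("assigned", "any"),
                        partial_policy = c("not_benign", "benign")) {
  stopifnot(therapeutic_threshold > 0, therapeutic_threshold < 1,
            exposure_threshold > 0, exposure_threshold < 1)
  structure(list(
    therapeutic_threshold = therapeutic_threshold,
    exposure_threshold = exposure_threshold,
    germline_mode = match.arg(germline_mode),
    partial_policy = match.arg(partial_policy)
  ), class = "flag_config")
}

#' Germline low-risk flag
#'
#' A motif hit is flagged when every one of its residues is present, with
#' the identical amino acid at the identical IMGT position (number and
#' insertion code), in a consulted human germline segment. Under
#' `mode = "assigned"` the consulted segments are the chain's assigned top
#' V and top J; under `mode = "any"`, every segment of the reference.
#' Because the D segment is not consulted, most of CDR-H3 can never match.
#' Hits without residues (`mCys`) are never flagged (`NA`).
#'
#' @param hits Hits tibble carrying `chain_id` (joinable to `chains`).
#' @param chains Chain tibble with `v_call`/`j_call`.
#' @param germ A germline reference: a chain tibble whose `chain_id` is the
#'   segment name (e.g. `"IGHV3-23*01"`), with `segment_type` column
#'   (`"V"`/`"J"`).
#' @param mode `"assigned"` or `"any"`.
#' @return Logical vector, one element per hit (`NA` for hits with no
#'   residues).
#' @export
flag_germline <- function(hits, chains, germ, mode = c("assigned", "any")) {
  mode <- match.arg(mode)
  if (!nrow(hits)) return(logical(0))
  # per-segment lookup: segment -> set of "label:residue" keys
  seg_keys <- germ |>
    dplyr::mutate(key = paste0(imgt_label(.data$position, .data$insertion),
                               ":", .data$residue)) |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(keys = list(.data$key), .groups = "drop")
  key_of <- stats::setNames(seg_keys$keys, seg_keys$chain_id)
  calls <- chains |>
    dplyr::distinct(.data$chain_id, .data$v_call, .data$j_call)
  vc <- stats::setNames(calls$v_call, calls$chain_id)
  jc <- stats::setNames(calls$j_call, calls$chain_id)

  hit_res <- hits_position_residues(hits)
  out <- rep(NA, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    pr <- hit_res[[i]]
    if (!length(pr)) next # mCys: nothing to match
    if (mode == "assigned") {
      v <- vc[[hits$chain_id[i]]]
      j <- jc[[hits$chain_id[i]]]
      if (is.na(v)) abort(paste0("unresolved germline: chain ",
                                 hits$chain_id[i], " has no v_call"))
      consulted <- unlist(key_of[stats::na.omit(c(v, j))],
                          use.names = FALSE)
      if (is.null(consulted)) {
        abort(paste0("unresolved germline: segment(s) for chain ",
                     hits$chain_id[i], " not in reference"))
      }
      out[i] <- all(pr %in% consulted)
    } else {
      consulted <- unlist(key_of, use.names = FALSE)
      out[i] <- all(pr %in% consulted)
    }
  }
  out
}

# per-hit "label:residue" keys
hits_position_residues <- function(hits) {
  purrr::map2(hits$positions, hits$matched, function(pos, m) {
    if (!length(pos)) return(character(0))
    paste0(pos, ":", strsplit(m, "")[[1]])
  })
}

#' Build a positional motif-frequency table from a therapeutic panel
#'
#' Scans every panel chain against the reference and records, for each
#' chain class (heavy vs pooled light) and each (motif tag, IMGT start),
#' the fraction of panel chains of that class carrying the motif there.
#' Each chain contributes at most once per (motif, position). Exact counts
#' and denominators are stored alongside the float frequency.
#'
#' @param panel QC-passed chain tibble of the marketed panel.
#' @param ref Liability reference.
#' @param policy CDR scope policy.
#' @return A tibble: `chain_class` (`"H"`/`"light"`), `motif_tag`,
#'   `imgt_start`, `count`, `denominator`, `frequency`.
#' @export
build_therapeutic_table <- function(panel, ref = liability_reference(),
                                    policy = "inclusive") {
  if (!nrow(panel)) abort("empty therapeutic panel")
  hits <- dplyr::bind_rows(scan_chains(panel, ref, policy),
                           check_conserved_cysteines(panel))
  classes <- panel |>
    dplyr::distinct(.data$chain_id, .data$chain_type) |>
    dplyr::mutate(chain_class = ifelse(.data$chain_type == "H", "H", "light"))
  denom <- classes |> dplyr::count(.data$chain_class, name = "denominator")
  hits <- hits |>
    dplyr::filter(!is.na(.data$start)) |>
    dplyr::left_join(classes[, c("chain_id", "chain_class")], by = "chain_id")
  tab <- hits |>
    dplyr::distinct(.data$chain_id, .data$chain_class, .data$motif_tag,
                    .data$imgt_start) |>
    dplyr::count(.data$chain_class, .data$motif_tag, .data$imgt_start,
                 name = "count") |>
    dplyr::left_join(denom, by = "chain_class") |>
    dplyr::mutate(frequency = .data$count / .data$denominator) |>
    dplyr::arrange(.data$chain_class, .data$motif_tag, .data$imgt_start)
  tab
}

#' Read/write a positional frequency table
#'
#' TSV with columns chain_class, motif_tag, imgt_start, count, denominator,
#' frequency; the exact rational counts travel with the float.
#'
#' @param path File path.
#' @return The table tibble.
#' @export
read_therapeutic_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chain_class = readr::col_character(),
    motif_tag = readr::col_character(),
    imgt_start = readr::col_character(),
    count = readr::col_integer(),
    denominator = readr::col_integer(),
    frequency = readr::col_double()), progress = FALSE)
}

#' @rdname read_therapeutic_table
#' @param table The table tibble.
#' @export
write_therapeutic_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' Therapeutic low-risk flag
#'
#' A hit is flagged when its (chain class, motif tag, IMGT start) frequency
#' in the marketed-panel table is strictly greater than the configured
#' threshold (default 5%). Entries absent from the table have frequency 0.
#' Hits without residues (`mCys`) are never flagged (`NA`).
#'
#' @param hits Hits tibble with a `chain_type` column (as produced by
#'   [profile_antibody()]), or pass `chain_type` explicitly.
#' @param table Positional frequency table from
#'   [build_therapeutic_table()].
#' @param config A [flag_config()].
#' @param chain_type Optional chain type per hit, if `hits` lacks the
#'   column.
#' @return Logical vector, one element per hit.
#' @export
flag_therapeutic <- function(hits, table, config = flag_config(),
                             chain_type = NULL) {
  if (!nrow(hits)) return(logical(0))
  ct <- chain_type %||% hits$chain_type
  if (is.null(ct)) abort("hits need a chain_type column")
  cls <- ifelse(ct == "H", "H", "light")
  key <- paste(cls, hits$motif_tag, hits$imgt_start, sep = "\r")
  tkey <- paste(table$chain_class, table$motif_tag, table$imgt_start,
                sep = "\r")
  freq <- table$frequency[match(key, tkey)]
  freq[is.na(freq)] <- 0
  out <- freq > config$therapeutic_threshold
  out[hits$rule_kind == "conserved_cys_missing"] <- NA
  out
}

#' Is a hit benign under a flag combination?
#'
#' A hit is benign under a combination when any applied flag in it marks
#' the hit low-risk: `germline = TRUE`, `therapeutic = TRUE`, or
#' `surface = "buried"` (plus `"partial"` when `partial_policy` is
#' `"benign"`). The empty combination marks nothing benign.
#'
#' @param hits Hits tibble with flag columns.
#' @param combo Character vector among `"germline"`, `"therapeutic"`,
#'   `"surface"` (may be empty).
#' @param config A [flag_config()].
#' @return Logical vector per hit.
#' @export
benign_under <- function(hits, combo = character(0),
                         config = flag_config()) {
  out <- rep(FALSE, nrow(hits))
  if ("germline" %in% combo) {
    out <- out | (!is.na(hits$germline) & hits$germline)
  }
  if ("therapeutic" %in% combo) {
    out <- out | (!is.na(hits$therapeutic) & hits$therapeutic)
  }
  if ("surface" %in% combo) {
    benign_cls <- if (config$partial_policy == "benign")
      c("buried", "partial") else "buried"
    out <- out | (!is.na(hits$surface) & hits$surface %in% benign_cls)
  }
  out
}
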