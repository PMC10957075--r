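empty_hits <- function() {
  tibble(
    chain_id = character(0), motif_tag = character(0),
    severity = character(0), rule_kind = character(0),
    start = integer(0), length = integer(0),
    imgt_start = character(0), matched = character(0),
    positions = list(), attribution = character(0),
    germline = logical(0), therapeutic = logical(0),
    surface = character(0)
  )
}

#' Scan numbered chains for liability motifs
#'
#' Every `motif_scan` entry of the reference is matched against each chain's
#' residue string in sequence order: adjacency is chain adjacency, so motifs
#' are found even across IMGT numbering gaps. Overlapping occurrences and
#' occurrences of different motifs on the same residues are all reported
#' independently. A `cdrs`-scope match is reported under the default
#' `"inclusive"` policy when at least one matched residue lies in a CDR
#' (capturing boundary liabilities); under `"strict"` all residues must be
#' in a CDR. `fv`-scope motifs are reported anywhere in 1-128.
#'
#' @param chains A QC-passed chain tibble.
#' @param ref A liability reference (default [liability_reference()]).
#' @param policy CDR scope policy, `"inclusive"` (default) or `"strict"`.
#' @return A hits tibble: `chain_id`, `motif_tag`, `severity`, `rule_kind`,
#'   `start` (residue index in the chain), `length`, `imgt_start` (IMGT
#'   label of the first residue), `matched` (the matched string),
#'   `positions` (list of IMGT labels), `attribution`
#'   (`framework`/`cdr`/`boundary`), and unset flag columns `germline`,
#'   `therapeutic`, `surface`.
#' @export
scan_chains <- function(chains, ref = liability_reference(),
                        policy = c("inclusive", "strict")) {
  policy <- match.arg(policy)
  if (!nrow(chains)) return(empty_hits())
  scan <- ref[ref$rule_kind == "motif_scan", ]
  out <- chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::group_map(~ scan_one_chain(.x, .y$chain_id, scan, policy)) |>
    dplyr::bind_rows()
  if (!nrow(out)) return(empty_hits())
  # restore input chain order
  out <- out[order(match(out$chain_id, unique(chains$chain_id)),
                   out$start), , drop = FALSE]
  out
}

scan_one_chain <- function(chain, chain_id, scan, policy) {
  s <- paste0(chain$residue, collapse = "")
  labels <- imgt_label(chain$position, chain$insertion)
  in_cdr <- startsWith(imgt_region(chain$position), "CDR")
  rows <- list()
  for (i in seq_len(nrow(scan))) {
    for (branch in pattern_branches(scan$pattern[i])) {
      len <- length(pattern_tokens(branch))
      starts <- branch_starts(s, branch)
      for (st in starts) {
        idx <- st:(st + len - 1L)
        cdr_cover <- in_cdr[idx]
        if (scan$scope[i] == "cdrs") {
          keep <- if (policy == "inclusive") any(cdr_cover) else all(cdr_cover)
          if (!keep) next
        }
        rows[[length(rows) + 1L]] <- tibble(
          chain_id = chain_id, motif_tag = scan$tag[i],
          severity = scan$severity[i], rule_kind = "motif_scan",
          start = st, length = len,
          imgt_start = labels[st],
          matched = substr(s, st, st + len - 1L),
          positions = list(labels[idx]),
          attribution = attribute_region_flags(cdr_cover),
          germline = NA, therapeutic = NA, surface = NA_character_
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

attribute_region_flags <- function(cdr_cover) {
  if (all(cdr_cover)) "cdr" else if (!any(cdr_cover)) "framework" else
    "boundary"
}

# All (overlapping) start indices of a fixed-length branch pattern.
branch_starts <- function(s, branch) {
  m <- gregexpr(paste0("(?=", branch, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Check the conserved cysteines at IMGT 23 and 104
#'
#' Emits one high-severity `mCys` hit per missing conserved cysteine
#' (position 23 or 104 lacking a cysteine, or absent altogether) and one
#' high-severity `xCys` hit per cysteine at any other position. `mCys` hits
#' carry no residues; attribution is `fv` for both.
#'
#' @param chains A QC-passed chain tibble.
#' @return A hits tibble (see [scan_chains()]).
#' @export
check_conserved_cysteines <- function(chains) {
  if (!nrow(chains)) return(empty_hits())
  rows <- list()
  for (cid in unique(chains$chain_id)) {
    chain <- chains[chains$chain_id == cid, ]
    labels <- imgt_label(chain$position, chain$insertion)
    is_cons <- labels %in% c("23", "104")
    for (p in c("23", "104")) {
      hit <- labels == p & chain$residue == "C"
      if (!any(hit)) {
        rows[[length(rows) + 1L]] <- tibble(
          chain_id = cid, motif_tag = "mCys", severity = "high",
          rule_kind = "conserved_cys_missing",
          start = NA_integer_, length = 0L, imgt_start = p,
          matched = NA_character_, positions = list(character(0)),
          attribution = "fv",
          germline = NA, therapeutic = NA, surface = NA_character_
        )
      }
    }
    extra <- which(chain$residue == "C" & !is_cons)
    for (ix in extra) {
      rows[[length(rows) + 1L]] <- tibble(
        chain_id = cid, motif_tag = "xCys", severity = "high",
        rule_kind = "conserved_cys_extra",
        start = ix, length = 1L, imgt_start = labels[ix],
        matched = "C", positions = list(labels[ix]),
        attribution = "fv",
        germline = NA, therapeutic = NA, surface = NA_character_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) empty_hits() else out
}

#' Profile an antibody unit (or a whole dataset of units)
#'
#' Runs motif scanning and the conserved-cysteine checks over every chain,
#' then applies the requested low-risk flags. The germline and therapeutic
#' flags are sequence-based and always applicable; the surface flag
#' requires a cognate heavy/light pair plus a structure (or precomputed
#' exposures), since unpaired interface residues would be misclassified as
#' exposed.
#'
#' @param chains QC-passed chain tibble; paired chains share a `unit_id`.
#' @param ref Liability reference.
#' @param flags Character vector among `"germline"`, `"therapeutic"`,
#'   `"surface"`; flags not listed stay `NA`.
#' @param germline A germline reference chain tibble (for `"germline"`).
#' @param therapeutic_table A positional frequency table (for
#'   `"therapeutic"`).
#' @param exposures A residue-exposure tibble from [residue_exposure()]
#'   (for `"surface"`).
#' @param config A [flag_config()].
#' @param policy CDR scope policy, see [scan_chains()].
#' @return An object of class `liab_profile`: a list with `hits` (flagged
#'   hits tibble), `units` (tibble of unit metadata incl. zero-liability
#'   units), `chains`, and `config`.
#' @export
profile_antibody <- function(chains, ref = liability_reference(),
                             flags = c("germline", "therapeutic"),
                             germline = NULL, therapeutic_table = NULL,
                             exposures = NULL, config = flag_config(),
                             policy = "inclusive") {
  flags <- match.arg(flags, c("germline", "therapeutic", "surface"),
                     several.ok = TRUE)
  chains <- dplyr::mutate(
    chains,
    unit_id = dplyr::coalesce(.data$unit_id, .data$chain_id))
  if ("surface" %in% flags) {
    per_unit <- chains |>
      dplyr::distinct(.data$unit_id, .data$chain_id, .data$chain_type)
    ok <- all(tapply(per_unit$chain_type, per_unit$unit_id, function(t)
      sum(t == "H") == 1L && sum(t %in% c("K", "L")) == 1L))
    if (!ok) {
      abort(paste0("surface flag requires cognate heavy/light pairs: ",
                   "supply paired chains (one H and one K/L per unit)"))
    }
    if (is.null(exposures)) {
      abort("surface flag requires a structure: supply `exposures`")
    }
  }
  if ("germline" %in% flags && is.null(germline)) {
    abort("germline flag requires a germline reference: supply `germline`")
  }
  if ("therapeutic" %in% flags && is.null(therapeutic_table)) {
    abort(paste0("therapeutic flag requires a positional frequency table: ",
                 "supply `therapeutic_table`"))
  }
  hits <- dplyr::bind_rows(scan_chains(chains, ref, policy),
                           check_conserved_cysteines(chains))
  meta <- chains |>
    dplyr::distinct(.data$chain_id, .data$unit_id, .data$chain_type,
                    .data$v_call, .data$j_call, .data$species_label)
  hits <- dplyr::left_join(hits, meta, by = "chain_id")
  if ("germline" %in% flags && nrow(hits)) {
    hits$germline <- flag_germline(hits, chains, germline,
                                   mode = config$germline_mode)
  }
  if ("therapeutic" %in% flags && nrow(hits)) {
    hits$therapeutic <- flag_therapeutic(hits, therapeutic_table, config)
  }
  if ("surface" %in% flags && nrow(hits)) {
    hits$surface <- flag_surface(hits, exposures)
  }
  units <- meta |>
    dplyr::group_by(.data$unit_id) |>
    dplyr::summarise(
      chain_types = paste(sort(.data$chain_type), collapse = "+"),
      species_label = dplyr::first(.data$species_label),
      v_call = dplyr::first(.data$v_call),
      .groups = "drop")
  structure(list(hits = hits, units = units, chains = chains,
                 config = config, flags_applied = flags),
            class = "liab_profile")
}

#' @export
print.liab_profile <- function(x, ...) {
  cat("<liab_profile> ", nrow(x$units), " unit(s), ",
      nrow(x$hits), " liability hit(s); flags applied: ",
      paste(x$flags_applied, collapse = ", "), "\n", sep = "")
  sev <- table(factor(x$hits$severity, levels = .severity_levels))
  cat("  severity:", paste(names(sev), sev, sep = "=", collapse = " "), "\n")
  invisible(x)
}
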