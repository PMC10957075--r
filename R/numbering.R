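#' IMGT region boundaries for the variable domain
#'
#' The standard IMGT delimitation of the variable domain (positions 1-128):
#' FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
#' FR4 118-128. Regions are contiguous, non-overlapping and cover 1-128.
#'
#' @return A tibble with columns `region`, `start`, `end`.
#' @export
imgt_region_bounds <- function() {
  tibble(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = c(1L, 27L, 39L, 56L, 66L, 105L, 118L),
    end = c(26L, 38L, 55L, 65L, 104L, 117L, 128L)
  )
}

#' Region of an IMGT position
#'
#' Insertion codes (e.g. "111A") inherit the region of their base number.
#'
#' @param position Integer positions 1-128, or position labels such as
#'   `"56"`, `"111A"`.
#' @return Character vector of region labels.
#' @export
#' @examples
#' imgt_region(c(27, 104, 112))
#' imgt_region("111A")
imgt_region <- function(position) {
  num <- if (is.character(position)) parse_imgt_label(position)$number
         else as.integer(position)
  if (any(is.na(num) | num < 1L | num > 128L)) {
    abort("IMGT position numbers must lie in 1-128")
  }
  b <- imgt_region_bounds()
  b$region[findInterval(num, b$start)]
}

# "111A" -> list(number = 111L, insertion = "A"); "56" -> insertion "".
parse_imgt_label <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)([A-Z]*)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) abort(paste0("malformed IMGT position label: ", label[bad][1]))
  list(number = as.integer(vapply(m, `[`, "", 2L)),
       insertion = vapply(m, `[`, "", 3L))
}

imgt_label <- function(number, insertion = "") {
  paste0(number, ifelse(is.na(insertion), "", insertion))
}

#' Attribute a run of positions to framework, CDR, or the boundary
#'
#' A motif occurrence is attributed `cdr` when all its residues lie in a
#' CDR, `framework` when none does, and `boundary` when it straddles the
#' two (one residue in the framework, the other in the CDR).
#'
#' @param positions Positions of the residues (numbers or labels), from one
#'   chain.
#' @return One of `"framework"`, `"cdr"`, `"boundary"`.
#' @export
#' @examples
#' attribute_region(c(56, 57))
#' attribute_region(c(38, 39))
attribute_region <- function(positions) {
  if (!length(positions)) abort("attribute_region() needs >= 1 position")
  in_cdr <- startsWith(imgt_region(positions), "CDR")
  if (all(in_cdr)) "cdr" else if (!any(in_cdr)) "framework" else "boundary"
}

#' Construct a numbered-chain tibble
#'
#' Chains are represented long: one row per residue, ordered as in the
#' polypeptide. Motif adjacency is defined on this row order, not on IMGT
#' numeric adjacency, so numbering gaps never split a motif.
#'
#' @param chain_id Chain identifier.
#' @param chain_type One of `"H"`, `"K"`, `"L"`.
#' @param position Integer IMGT numbers (1-128), parallel to `residue`.
#' @param residue Single-letter residues (standard 20 only).
#' @param insertion Insertion codes (`""` for none), parallel to `residue`.
#' @param v_call,j_call Optional germline V / J assignment names.
#' @param species_label Optional `"human"` / `"nonhuman"` label.
#' @param unit_id Optional antibody-unit (molecule) identifier for paired data.
#' @return A chain tibble.
#' @export
numbered_chain <- function(chain_id, chain_type, position, residue,
                           insertion = "", v_call = NA_character_,
                           j_call = NA_character_,
                           species_label = NA_character_,
                           unit_id = NA_character_) {
  if (!chain_type %in% c("H", "K", "L")) {
    abort(paste0("unknown chain type: ", chain_type))
  }
  position <- as.integer(position)
  if (any(position < 1L | position > 128L)) {
    abort("IMGT position numbers must lie in 1-128")
  }
  if (any(!residue %in% aa_standard)) {
    abort("residues must be standard amino acids")
  }
  tibble(
    chain_id = chain_id, chain_type = chain_type,
    position = position,
    insertion = rep_len(insertion, length(position)),
    residue = residue,
    v_call = v_call, j_call = j_call,
    species_label = species_label, unit_id = unit_id
  )
}

#' One-letter sequence string of each chain
#'
#' @param chains A chain tibble (possibly many chains).
#' @return A tibble with `chain_id` and `sequence`.
#' @export
chain_sequences <- function(chains) {
  chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(sequence = paste0(.data$residue, collapse = ""),
                     .groups = "drop")
}

#' Read pre-numbered chains
#'
#' Numbering itself is delegated to external tools; this parses their
#' tabular output. Two dialects are supported:
#'
#' * `airr_tsv`: AIRR-Rearrangement-style TSV with columns `sequence_id`,
#'   `locus` (IGH/IGK/IGL or H/K/L), `sequence_alignment_aa` (the
#'   IMGT-gapped amino-acid alignment, `.` for gaps, character i = IMGT
#'   position i), and optional `v_call`, `j_call`, `species_label`,
#'   `unit_id`. This dialect cannot carry insertion codes.
#' * `anarci_csv`: wide CSV with columns `sequence_id`, `chain_type`,
#'   optional `v_call`/`j_call`/`species_label`/`unit_id`, then one column
#'   per IMGT position label (`1`, `2`, ..., `111A`, ...), `-` for absent.
#'   Insertion order is taken from the column order and never re-sorted.
#'
#' Malformed records (unknown chain type, residue outside the standard 20,
#' position outside 1-128) are rejected per record, not fatally.
#'
#' @param path File path.
#' @param dialect `"airr_tsv"` or `"anarci_csv"`.
#' @return `list(chains = <chain tibble>, rejected = tibble(id, reason))`.
#' @export
read_numbered_chains <- function(path, dialect = c("airr_tsv", "anarci_csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "airr_tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    parse_airr_records(raw)
  } else {
    raw <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    parse_anarci_records(raw)
  }
}

locus_to_chain_type <- function(locus) {
  up <- toupper(locus)
  out <- dplyr::case_when(
    up %in% c("IGH", "H") ~ "H",
    up %in% c("IGK", "K") ~ "K",
    up %in% c("IGL", "L") ~ "L",
    TRUE ~ NA_character_
  )
  out
}

parse_airr_records <- function(raw) {
  chains <- list()
  rejected <- list()
  opt <- function(row, col) {
    if (col %in% names(row) && !is.na(row[[col]])) row[[col]] else NA_character_
  }
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    id <- row$sequence_id
    ct <- locus_to_chain_type(row$locus)
    if (is.na(ct)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "unknown chain type")
      next
    }
    aln <- strsplit(row$sequence_alignment_aa, "")[[1]]
    keep <- aln != "."
    pos <- which(keep)
    res <- aln[keep]
    if (any(pos > 128L)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "position outside 1-128")
      next
    }
    if (any(!res %in% aa_standard)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "non-standard residue")
      next
    }
    chains[[length(chains) + 1L]] <- numbered_chain(
      id, ct, pos, res,
      v_call = opt(row, "v_call"), j_call = opt(row, "j_call"),
      species_label = opt(row, "species_label"),
      unit_id = opt(row, "unit_id")
    )
  }
  list(chains = dplyr::bind_rows(chains), rejected = dplyr::bind_rows(rejected))
}

parse_anarci_records <- function(raw) {
  meta_cols <- intersect(
    c("sequence_id", "chain_type", "v_call", "j_call", "species_label",
      "unit_id"), names(raw))
  pos_cols <- setdiff(names(raw), meta_cols)
  lab <- parse_imgt_label(pos_cols)
  chains <- list()
  rejected <- list()
  opt <- function(row, col) {
    if (col %in% names(row) && !is.na(row[[col]])) row[[col]] else NA_character_
  }
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    id <- row$sequence_id
    ct <- row$chain_type
    if (is.na(ct) || !ct %in% c("H", "K", "L")) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "unknown chain type")
      next
    }
    res <- unname(unlist(row[pos_cols]))
    keep <- !is.na(res) & res != "-"
    if (any(lab$number[keep] < 1L | lab$number[keep] > 128L)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "position outside 1-128")
      next
    }
    if (any(!res[keep] %in% aa_standard)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(id = id, reason = "non-standard residue")
      next
    }
    chains[[length(chains) + 1L]] <- numbered_chain(
      id, ct, lab$number[keep], res[keep], insertion = lab$insertion[keep],
      v_call = opt(row, "v_call"), j_call = opt(row, "j_call"),
      species_label = opt(row, "species_label"),
      unit_id = opt(row, "unit_id")
    )
  }
  list(chains = dplyr::bind_rows(chains), rejected = dplyr::bind_rows(rejected))
}

#' Write numbered chains in the wide numbered-CSV dialect
#'
#' Position columns appear in the residue order of the first occurrence
#' across chains, so insertion ordering round-trips.
#'
#' @param chains A chain tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_numbered_chains <- function(chains, path) {
  chains <- dplyr::mutate(chains,
                          label = imgt_label(.data$position, .data$insertion))
  # global column order: by base number, then first-seen order of insertions
  labs <- chains |>
    dplyr::distinct(.data$position, .data$label) |>
    dplyr::arrange(.data$position)
  wide <- chains |>
    dplyr::select("chain_id", "chain_type", "v_call", "j_call",
                  "species_label", "unit_id", "label", "residue") |>
    tidyr::pivot_wider(names_from = "label", values_from = "residue",
                       values_fill = "-")
  wide <- wide[, c("chain_id", "chain_type", "v_call", "j_call",
                   "species_label", "unit_id", labs$label)]
  names(wide)[1] <- "sequence_id"
  readr::write_csv(wide, path, na = "", progress = FALSE)
  invisible(path)
}
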