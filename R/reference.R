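#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

#' The twenty standard amino acids
#'
#' Single-letter codes of the 20 standard amino acids, the only residue
#' alphabet accepted throughout the package.
#'
#' @format Character vector of length 20.
#' @export
aa_standard <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.severity_levels <- c("high", "medium", "low")
.scope_levels <- c("cdrs", "fv")
.rule_kinds <- c("motif_scan", "conserved_cys_missing", "conserved_cys_extra")

#' Load the default antibody liability reference
#'
#' The reference codifies 13 liability categories: deamidation at three
#' severities, fragmentation at two, and isomerization, hydrolysis,
#' tryptophan/methionine oxidation, N-linked glycosylation sequons,
#' integrin-binding motifs, and the two conserved-cysteine rules (missing
#' at IMGT 23/104, extra elsewhere). Motif patterns use a deliberately small
#' dialect: literal residues, bracketed classes, one-level negation and
#' top-level alternation, so that the full expansion of every pattern is
#' finite (see [expand_pattern()]).
#'
#' @param path Path to a reference file (see [read_liability_reference()]).
#'   Defaults to the reference shipped with the package.
#' @return A tibble with columns `tag`, `name`, `severity`, `pattern`,
#'   `scope`, `rule_kind`.
#' @export
#' @examples
#' liability_reference()
liability_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "liability_reference.tsv",
                                package = "abliab", mustWork = TRUE)
  read_liability_reference(path)
}

#' Read a liability reference file
#'
#' Tab-separated UTF-8 text with columns tag/name/severity/pattern/scope/
#' rule_kind; `#` starts a comment line. The file is validated: tags must be
#' unique, severities/scopes/rule kinds must come from their closed
#' enumerations, and a pattern must be present if and only if the rule kind
#' is `motif_scan`.
#'
#' @param path File path.
#' @return A validated reference tibble.
#' @export
read_liability_reference <- function(path) {
  ref <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    tag = readr::col_character(), name = readr::col_character(),
    severity = readr::col_character(), pattern = readr::col_character(),
    scope = readr::col_character(), rule_kind = readr::col_character()
  ), na = character(), progress = FALSE)
  validate_liability_reference(as_tibble(ref))
}

#' Write a liability reference file
#'
#' @param ref A reference tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_liability_reference <- function(ref, path) {
  ref <- validate_liability_reference(ref)
  readr::write_tsv(ref, path, progress = FALSE)
  invisible(path)
}

#' Validate a liability reference
#'
#' @param ref A tibble with the reference columns.
#' @return The reference, invisibly checked.
#' @export
validate_liability_reference <- function(ref) {
  needed <- c("tag", "name", "severity", "pattern", "scope", "rule_kind")
  missing <- setdiff(needed, names(ref))
  if (length(missing)) {
    abort(paste0("reference is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- ref$tag[duplicated(ref$tag)]
  if (length(dup)) {
    abort(paste0("duplicate tag(s) in reference: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- ref$tag[!ref$severity %in% .severity_levels]
  if (length(bad)) abort(paste0("invalid severity for entry: ", bad[1]))
  bad <- ref$tag[!ref$scope %in% .scope_levels]
  if (length(bad)) abort(paste0("invalid scope for entry: ", bad[1]))
  bad <- ref$tag[!ref$rule_kind %in% .rule_kinds]
  if (length(bad)) abort(paste0("invalid rule_kind for entry: ", bad[1]))
  has_pat <- !is.na(ref$pattern) & nzchar(ref$pattern)
  bad <- ref$tag[xor(has_pat, ref$rule_kind == "motif_scan")]
  if (length(bad)) {
    abort(paste0("pattern must be non-empty iff rule_kind is motif_scan; ",
                 "offending entry: ", bad[1]))
  }
  scan <- ref[ref$rule_kind == "motif_scan", ]
  for (i in seq_len(nrow(scan))) {
    branches <- pattern_branches(scan$pattern[i])
    for (b in branches) {
      toks <- tryCatch(pattern_tokens(b), error = function(e) {
        abort(paste0("unparseable pattern for entry ", scan$tag[i], ": ",
                     conditionMessage(e)))
      })
      if (!length(toks)) abort(paste0("empty branch in entry ", scan$tag[i]))
    }
  }
  ref
}

# Split a pattern on top-level alternation.
pattern_branches <- function(pattern) {
  strsplit(pattern, "|", fixed = TRUE)[[1]]
}

# Tokenize one alternation branch into literals and classes.
pattern_tokens <- function(branch) {
  toks <- character(0)
  i <- 1L
  n <- nchar(branch)
  while (i <= n) {
    ch <- substr(branch, i, i)
    if (ch == "[") {
      j <- regexpr("]", substr(branch, i, n), fixed = TRUE)
      if (j < 0) stop("unterminated class in '", branch, "'", call. = FALSE)
      toks <- c(toks, substr(branch, i, i + j - 1L))
      i <- i + j
    } else if (ch %in% aa_standard) {
      toks <- c(toks, ch)
      i <- i + 1L
    } else {
      stop("unexpected character '", ch, "' in '", branch, "'", call. = FALSE)
    }
  }
  toks
}

# Residues a single token stands for.
token_residues <- function(token) {
  if (startsWith(token, "[^")) {
    inner <- strsplit(substr(token, 3L, nchar(token) - 1L), "")[[1]]
    setdiff(aa_standard, inner)
  } else if (startsWith(token, "[")) {
    strsplit(substr(token, 2L, nchar(token) - 1L), "")[[1]]
  } else {
    token
  }
}

#' Expand a motif pattern into the explicit strings it matches
#'
#' The pattern dialect has no quantifiers, so every pattern expands into a
#' finite set of concrete residue strings; negated classes expand over the
#' 19 permitted residues. Used by the brute-force scanning oracle and for
#' documentation.
#'
#' @param pattern A pattern string, or a one-row reference entry (tibble/list
#'   with `pattern` and `rule_kind`).
#' @return Character vector of distinct concrete strings.
#' @export
#' @examples
#' expand_pattern("N[GS]")
expand_pattern <- function(pattern) {
  if (is.list(pattern)) {
    if (!is.null(pattern$rule_kind) && pattern$rule_kind[1] != "motif_scan") {
      abort("expand_pattern() only supports motif_scan rules")
    }
    pattern <- pattern$pattern[1]
  }
  if (is.na(pattern) || !nzchar(pattern)) {
    abort("expand_pattern() only supports motif_scan rules")
  }
  out <- character(0)
  for (b in pattern_branches(pattern)) {
    sets <- lapply(pattern_tokens(b), token_residues)
    grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
    out <- c(out, apply(grid, 1L, paste0, collapse = ""))
  }
  unique(out)
}
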