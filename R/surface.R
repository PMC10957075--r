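#' Maximum accessible surface areas per residue type
#'
#' Theoretical maximum accessible surface areas (Angstrom^2) per residue
#' type (Tien et al. 2013, theoretical values), used to normalize absolute
#' SASA into relative SASA. Pinned as data for reproducibility.
#'
#' @return Named numeric vector over the 20 single-letter codes.
#' @export
max_asa_theoretical <- function() {
  c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    E = 223.0, Q = 225.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)
}

# Bondi van der Waals radii for the heavy atoms of proteins (Angstrom).
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radius <- function(element) {
  r <- .vdw_radii[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Deterministic golden-spiral (Fibonacci) unit-sphere lattice.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples a deterministic spiral point lattice on each heavy atom's
#' solvent-accessible sphere (van der Waals radius + probe) and counts the
#' points not occluded by any other atom. Hydrogens are ignored; dummy
#' (unmapped) atoms occlude but are not reported. Results are bit-stable
#' given `n_points`.
#'
#' @param atoms An atom tibble with columns `x`, `y`, `z`, `element`,
#'   `chain_role` (`"H"`/`"L"`), `position` (IMGT label), `residue`
#'   (one-letter code), `mapped` (logical; dummy/occluder atoms are
#'   `FALSE`). See [read_fv_structure()].
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Tibble: `chain_role`, `position`, `residue`, `abs_sasa`.
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960L) {
  if (!nrow(atoms)) abort("empty structure")
  pts <- fibonacci_sphere(n_points)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- vdw_radius(atoms$element) + probe_radius
  n <- nrow(atoms)
  area <- numeric(n)
  for (i in seq_len(n)) {
    if (!atoms$mapped[i]) next
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i)
    sp <- pts * rad[i]
    sp[, 1] <- sp[, 1] + xyz[i, 1]
    sp[, 2] <- sp[, 2] + xyz[i, 2]
    sp[, 3] <- sp[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  atoms$abs_sasa <- area
  atoms[atoms$mapped, , drop = FALSE] |>
    dplyr::group_by(.data$chain_role, .data$position) |>
    dplyr::summarise(residue = dplyr::first(.data$residue),
                     abs_sasa = sum(.data$abs_sasa), .groups = "drop")
}

#' Classify residue exposure from relative SASA
#'
#' A residue is `exposed` when its relative SASA is strictly greater than
#' the threshold (default 7.5%), otherwise `buried`.
#'
#' @param rel_sasa Non-negative relative SASA fraction(s).
#' @param config A [flag_config()].
#' @return Character vector `"exposed"`/`"buried"`.
#' @export
#' @examples
#' classify_exposure(c(0.075, 0.076))
classify_exposure <- function(rel_sasa, config = flag_config()) {
  if (any(rel_sasa < 0)) abort("rel_sasa must be non-negative")
  ifelse(rel_sasa > config$exposure_threshold, "exposed", "buried")
}

#' Per-residue exposure table for a paired-Fv structure
#'
#' Runs [compute_sasa()] on the full heavy+light complex and normalizes by
#' the residue type's theoretical maximum ASA.
#'
#' @param atoms Atom tibble (see [compute_sasa()]).
#' @param config A [flag_config()].
#' @param probe_radius,n_points Passed to [compute_sasa()].
#' @return Tibble: `chain_role`, `position`, `residue`, `abs_sasa`,
#'   `rel_sasa`, `exposure_class`.
#' @export
residue_exposure <- function(atoms, config = flag_config(),
                             probe_radius = 1.4, n_points = 960L) {
  sasa <- compute_sasa(atoms, probe_radius, n_points)
  sasa |>
    dplyr::mutate(
      rel_sasa = .data$abs_sasa /
        unname(max_asa_theoretical()[.data$residue]),
      exposure_class = classify_exposure(.data$rel_sasa, config))
}

#' Surface flag for liability hits
#'
#' A hit is `buried` when all its residues are buried, `exposed` when all
#' are exposed, `partial` when mixed, and `unknown` when any residue lacks
#' structure coverage or the hit has no residues (`mCys`).
#'
#' @param hits Hits tibble with `chain_type` per hit (H vs K/L decides the
#'   chain role).
#' @param exposures Exposure tibble from [residue_exposure()].
#' @return Character vector per hit.
#' @export
flag_surface <- function(hits, exposures) {
  if (!nrow(hits)) return(character(0))
  role <- ifelse(hits$chain_type == "H", "H", "L")
  ekey <- paste(exposures$chain_role, exposures$position, sep = "\r")
  cls <- stats::setNames(exposures$exposure_class, ekey)
  vapply(seq_len(nrow(hits)), function(i) {
    pos <- hits$positions[[i]]
    if (!length(pos)) return("unknown")
    c_i <- cls[paste(role[i], pos, sep = "\r")]
    if (any(is.na(c_i))) return("unknown")
    if (all(c_i == "buried")) "buried"
    else if (all(c_i == "exposed")) "exposed"
    else "partial"
  }, character(1))
}

#' Read a paired-Fv PDB structure
#'
#' Parses a two-chain PDB file (via bio3d) whose residue numbers are
#' assumed IMGT-mapped (the convention of common Fv modelling tools).
#' Hydrogens are dropped; residues in chains other than the two named ones
#' are kept as unmapped occluders.
#'
#' @param path PDB file path.
#' @param heavy,light PDB chain identifiers of the heavy and light chains.
#' @return Atom tibble for [compute_sasa()].
#' @export
read_fv_structure <- function(path, heavy = "H", light = "L") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- as_tibble(pdb$atom)
  elem <- if ("elesy" %in% names(at) && any(nzchar(trimws(at$elesy)))) {
    trimws(at$elesy)
  } else {
    substr(trimws(at$elety), 1, 1)
  }
  at$element <- elem
  at <- at[at$element != "H", , drop = FALSE]
  aa1 <- vapply(at$resid, function(r) {
    out <- suppressWarnings(bio3d::aa321(r))
    if (is.na(out) || out == "X") NA_character_ else out
  }, character(1))
  role <- dplyr::case_when(at$chain == heavy ~ "H",
                           at$chain == light ~ "L",
                           TRUE ~ NA_character_)
  tibble(
    x = at$x, y = at$y, z = at$z, element = at$element,
    chain_role = role,
    position = imgt_label(at$resno, ifelse(is.na(at$insert) |
                                             at$insert == "", "",
                                           at$insert)),
    residue = unname(aa1),
    occupancy = at$o %||% 1,
    mapped = !is.na(role) & !is.na(aa1)
  )
}

#' Write an atom tibble as a PDB file
#'
#' Thin wrapper over bio3d's PDB writer; mapped residues go to their chain
#' role, unmapped occluder atoms to chain `"X"` as UNK residues.
#'
#' @param atoms Atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fv_structure <- function(atoms, path) {
  aa3 <- vapply(atoms$residue, function(r)
    if (is.na(r)) "UNK" else bio3d::aa123(r), character(1))
  lab <- parse_imgt_label(ifelse(is.na(atoms$position), "1", atoms$position))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    resno = lab$number,
    insert = ifelse(lab$insertion == "", "", lab$insertion),
    chain = ifelse(is.na(atoms$chain_role), "X", atoms$chain_role),
    resid = aa3,
    elety = ifelse(atoms$element == "C", "CA", atoms$element),
    elesy = atoms$element,
    o = atoms$occupancy %||% 1)
  invisible(path)
}
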