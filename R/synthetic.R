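#' Synthetic fixtures
#'
#' The generators in this module build every input the pipeline consumes —
#' germline sets, planted-motif chains, therapeutic panels with controlled
#' positional frequencies, toy structures with known burial, and benchmark
#' records with a known effect direction — entirely in code, with an exact
#' ledger of everything planted. Background residues are drawn from a
#' scaffold alphabet ({E, F, I, L, Q, V}) chosen so that no default-reference
#' motif can arise by accident, which makes ledger comparisons exact.
#'
#' @name synthetic
NULL

.scaffold_alphabet <- c("E", "F", "I", "L", "Q", "V")

# Canonical planted string per motif tag: each produces exactly one hit and
# cannot combine with scaffold neighbours (given a 2-residue margin) into a
# second motif.
.plant_strings <- c(
  DeAmdH = "NG", FragH = "DP", Isom = "DH", Ngly = "NQT", DeAmdM = "NH",
  Hydro = "NP", FragM = "TS", TrpOx = "W", MetOx = "M", DeAmdL = "SN",
  IntBind = "RGD", xCys = "C"
)

.region_indices <- function(region) {
  b <- imgt_region_bounds()
  r <- b[b$region == region, ]
  if (!nrow(r)) abort(paste0("unknown region: ", region))
  seq.int(r$start, r$end)
}

# Place `str` at positions start..start+len-1 of a residue vector, marking
# an occupancy margin of 2 on each side.
.place <- function(residues, occupied, start, str) {
  len <- nchar(str)
  idx <- start:(start + len - 1L)
  if (any(occupied[idx])) return(NULL)
  residues[idx] <- strsplit(str, "")[[1]]
  lo <- max(1L, start - 2L)
  hi <- min(length(residues), start + len + 1L)
  occupied[lo:hi] <- TRUE
  list(residues = residues, occupied = occupied)
}

.fresh_template <- function(n = 128L) {
  residues <- sample(.scaffold_alphabet, n, replace = TRUE)
  occupied <- rep(FALSE, n)
  residues[c(23L, 104L)] <- "C"
  occupied[c(22L, 23L, 24L, 103L, 104L, 105L)] <- TRUE
  list(residues = residues, occupied = occupied)
}

.cdrs_scope_tags <- c("DeAmdH", "FragH", "Isom", "DeAmdM", "Hydro",
                      "FragM", "TrpOx", "MetOx", "DeAmdL")

.plant_plan_row <- function(tmpl, motif_tag, region = NA, imgt_start = NA,
                            indices = NULL) {
  if (motif_tag == "mCys") {
    pos <- if (!is.na(imgt_start)) as.integer(imgt_start) else 104L
    if (!pos %in% c(23L, 104L)) abort("mCys planting must target 23 or 104")
    tmpl$residues[pos] <- sample(.scaffold_alphabet, 1L)
    tmpl$occupied[pos] <- TRUE
    return(list(tmpl = tmpl, start = pos,
                matched = NA_character_, attribution = "fv"))
  }
  str <- .plant_strings[[motif_tag]]
  if (is.null(str)) abort(paste0("no planting string for motif ", motif_tag))
  len <- nchar(str)
  if (!is.null(indices)) {
    idx <- indices[indices + len - 1L <= max(indices)]
    starts <- sample(idx, length(idx))
  } else if (!is.na(imgt_start)) {
    starts <- as.integer(imgt_start)
  } else {
    idx <- .region_indices(region)
    idx <- idx[idx + len - 1L <= max(idx)]
    starts <- sample(idx, length(idx))
  }
  for (st in starts) {
    span <- st:(st + len - 1L)
    attribution <- if (motif_tag == "xCys") "fv" else attribute_region(span)
    if (motif_tag %in% .cdrs_scope_tags && attribution == "framework") {
      abort(paste0("unsatisfiable planting plan: ", motif_tag,
                   " is CDR-scoped but the target lies wholly in the ",
                   "framework"))
    }
    placed <- .place(tmpl$residues, tmpl$occupied, st, str)
    if (!is.null(placed)) {
      return(list(tmpl = placed, start = st, matched = str,
                  attribution = attribution))
    }
  }
  abort(paste0("unsatisfiable planting plan: no room for ", motif_tag,
               if (!is.na(region)) paste0(" in ", region) else ""))
}

# Expand a plan (motif_tag + region|imgt_start + count) to one row per plant.
.expand_plan <- function(plan) {
  if (is.null(plan) || !nrow(plan)) {
    return(tibble(motif_tag = character(0), region = character(0),
                  imgt_start = character(0)))
  }
  if (!"count" %in% names(plan)) plan$count <- 1L
  if (!"region" %in% names(plan)) plan$region <- NA_character_
  if (!"imgt_start" %in% names(plan)) plan$imgt_start <- NA_character_
  plan[rep(seq_len(nrow(plan)), plan$count),
       c("motif_tag", "region", "imgt_start"), drop = FALSE]
}

#' Generate a toy germline reference set
#'
#' Builds a small IMGT-numbered human germline set: V segments across
#' several heavy subgroups plus kappa/lambda (coverage FR1 through the
#' start of CDR3, positions 1-106, conserved cysteines at 23 and 104) and
#' J segments (CDR3 tail and FR4, positions 116-128). Each segment's
#' intrinsic liabilities are planted and ledgered.
#'
#' @param seed Integer seed; identical seeds give identical sets.
#' @return `list(segments = <chain tibble with segment_type>,
#'   ledger = tibble(segment, motif_tag, imgt_start, matched,
#'   attribution))`.
#' @export
make_toy_germline_set <- function(seed = 1L) {
  withr::with_seed(seed, {
    specs <- tibble(
      name = c("IGHV1-1*01", "IGHV1-2*01", "IGHV3-1*01", "IGHV3-2*01",
               "IGHV4-1*01", "IGKV1-1*01", "IGLV1-1*01"),
      chain_type = c("H", "H", "H", "H", "H", "K", "L")
    )
    # one intrinsic liability per CDR, planted in windows kept clear of
    # the CDR boundaries so chain-level plans can still target positions
    # like 38 or 56 without collisions
    pool_cdr1 <- tibble(motif_tag = c("DeAmdH", "MetOx", "DeAmdM"),
                        window = list(27:33, 27:33, 27:33))
    pool_cdr2 <- tibble(motif_tag = c("Isom", "FragM", "TrpOx"),
                        window = list(58:63, 58:63, 58:63))
    segments <- list()
    ledger <- list()
    for (i in seq_len(nrow(specs))) {
      tmpl <- .fresh_template(106L)
      rows <- dplyr::bind_rows(pool_cdr1[sample(nrow(pool_cdr1), 1L), ],
                               pool_cdr2[sample(nrow(pool_cdr2), 1L), ])
      for (k in seq_len(nrow(rows))) {
        res <- .plant_plan_row(tmpl, rows$motif_tag[k],
                               indices = rows$window[[k]])
        tmpl <- res$tmpl
        ledger[[length(ledger) + 1L]] <- tibble(
          segment = specs$name[i], motif_tag = rows$motif_tag[k],
          imgt_start = as.character(res$start), matched = res$matched,
          attribution = res$attribution)
      }
      segments[[i]] <- numbered_chain(
        specs$name[i], specs$chain_type[i], seq_len(106L), tmpl$residues)
      segments[[i]]$segment_type <- "V"
    }
    jspecs <- tibble(name = c("IGHJ1*01", "IGKJ1*01", "IGLJ1*01"),
                     chain_type = c("H", "K", "L"))
    for (i in seq_len(nrow(jspecs))) {
      res <- sample(.scaffold_alphabet, 13L, replace = TRUE)
      seg <- numbered_chain(jspecs$name[i], jspecs$chain_type[i],
                            116:128, res)
      seg$segment_type <- "J"
      segments[[length(segments) + 1L]] <- seg
    }
    list(segments = dplyr::bind_rows(segments),
         ledger = dplyr::bind_rows(ledger))
  })
}

#' Generate synthetic numbered chains with planted liability motifs
#'
#' Each chain covers IMGT 1-128, has conserved cysteines at 23/104, a
#' motif-free scaffold background, and the plan's motifs planted at
#' recorded positions. When a germline set is supplied, each chain is
#' derived from a seeded-random V and J segment of its chain type (so
#' germline-inherited liabilities are ledgered too, with
#' `origin = "germline"`, and are germline-flaggable at their original
#' positions).
#'
#' @param n Number of chains.
#' @param plan Planting plan applied to every chain: tibble with
#'   `motif_tag` and either `region` (motif placed wholly inside it) or
#'   `imgt_start` (explicit start, e.g. boundary planting), plus optional
#'   `count`.
#' @param seed Integer seed.
#' @param chain_type `"H"`, `"K"` or `"L"`.
#' @param germline Optional result of [make_toy_germline_set()].
#' @param id_prefix Chain id prefix.
#' @param unit_id Optional unit ids (recycled), for paired data.
#' @return `list(chains, ledger)`; the ledger has one row per expected
#'   hit: `chain_id`, `motif_tag`, `imgt_start`, `matched`,
#'   `attribution`, `origin`.
#' @export
generate_chains <- function(n, plan = NULL, seed = 1L, chain_type = "H",
                            germline = NULL, id_prefix = "syn",
                            unit_id = NA_character_) {
  plan <- .expand_plan(plan)
  withr::with_seed(seed, {
    chains <- list()
    ledger <- list()
    unit_id <- rep_len(unit_id, n)
    for (k in seq_len(n)) {
      cid <- sprintf("%s_%s%03d", id_prefix, chain_type, k)
      tmpl <- .fresh_template(128L)
      v_call <- "synthetic-V"; j_call <- "synthetic-J"
      if (!is.null(germline)) {
        segs <- germline$segments
        vs <- unique(segs$chain_id[segs$segment_type == "V" &
                                     segs$chain_type == chain_type])
        js <- unique(segs$chain_id[segs$segment_type == "J" &
                                     segs$chain_type == chain_type])
        v_call <- sample(vs, 1L); j_call <- sample(js, 1L)
        vseg <- segs[segs$chain_id == v_call, ]
        jseg <- segs[segs$chain_id == j_call, ]
        tmpl$residues[vseg$position] <- vseg$residue
        tmpl$residues[jseg$position] <- jseg$residue
        inh <- germline$ledger[germline$ledger$segment == v_call, ]
        for (r in seq_len(nrow(inh))) {
          st <- as.integer(inh$imgt_start[r])
          len <- if (is.na(inh$matched[r])) 1L else nchar(inh$matched[r])
          lo <- max(1L, st - 2L); hi <- min(128L, st + len + 1L)
          tmpl$occupied[lo:hi] <- TRUE
          ledger[[length(ledger) + 1L]] <- tibble(
            chain_id = cid, motif_tag = inh$motif_tag[r],
            imgt_start = inh$imgt_start[r], matched = inh$matched[r],
            attribution = inh$attribution[r], origin = "germline")
        }
      }
      for (r in seq_len(nrow(plan))) {
        res <- .plant_plan_row(tmpl, plan$motif_tag[r], plan$region[r],
                               plan$imgt_start[r])
        tmpl <- res$tmpl
        ledger[[length(ledger) + 1L]] <- tibble(
          chain_id = cid, motif_tag = plan$motif_tag[r],
          imgt_start = as.character(res$start), matched = res$matched,
          attribution = res$attribution, origin = "planted")
      }
      chains[[k]] <- numbered_chain(
        cid, chain_type, seq_len(128L), tmpl$residues,
        v_call = v_call, j_call = j_call, species_label = "human",
        unit_id = unit_id[k])
    }
    chains <- dplyr::bind_rows(chains)
    ledger <- if (length(ledger)) dplyr::bind_rows(ledger) else
      tibble(chain_id = character(0), motif_tag = character(0),
             imgt_start = character(0), matched = character(0),
             attribution = character(0), origin = character(0))
    .verify_ledger(chains, ledger)
    list(chains = chains, ledger = ledger)
  })
}

# The generator's guarantee: scanning recovers exactly the ledger.
.verify_ledger <- function(chains, ledger) {
  hits <- dplyr::bind_rows(scan_chains(chains),
                           check_conserved_cysteines(chains))
  got <- sort(paste(hits$chain_id, hits$motif_tag, hits$imgt_start))
  want <- sort(paste(ledger$chain_id, ledger$motif_tag, ledger$imgt_start))
  if (!identical(got, want)) {
    abort("internal error: generated chains do not reproduce their ledger")
  }
  invisible(TRUE)
}

#' Generate paired heavy+light units
#'
#' Convenience wrapper around [generate_chains()] producing `n` units of
#' one heavy and one kappa chain sharing a `unit_id`.
#'
#' @param n Number of units.
#' @param plan_h,plan_l Planting plans for the heavy and light chains.
#' @param seed Integer seed.
#' @param germline Optional toy germline set.
#' @return `list(chains, ledger)`.
#' @export
generate_paired_units <- function(n, plan_h = NULL, plan_l = NULL,
                                  seed = 1L, germline = NULL) {
  uid <- sprintf("unit%03d", seq_len(n))
  h <- generate_chains(n, plan_h, seed = seed, chain_type = "H",
                       germline = germline, id_prefix = "pair",
                       unit_id = uid)
  l <- generate_chains(n, plan_l, seed = seed + 1L, chain_type = "K",
                       germline = germline, id_prefix = "pair",
                       unit_id = uid)
  list(chains = dplyr::bind_rows(h$chains, l$chains),
       ledger = dplyr::bind_rows(h$ledger, l$ledger))
}

#' Generate a therapeutic panel with controlled positional frequencies
#'
#' Builds a panel of `n` chains per chain class in which each planned
#' (motif, IMGT start) occurs in exactly `frequency * n` chains; the
#' expected positional frequency table is returned for comparison with
#' [build_therapeutic_table()].
#'
#' @param plan Tibble: `motif_tag`, `imgt_start`, `frequency`, optional
#'   `chain_class` (`"H"` default, or `"light"`).
#' @param n Chains per chain class.
#' @param seed Integer seed.
#' @return `list(panel = <chain tibble>, expected = <frequency table>)`.
#' @export
generate_therapeutic_panel <- function(plan, n, seed = 1L) {
  if (n < 1L) abort("panel size n must be >= 1")
  if (!"chain_class" %in% names(plan)) plan$chain_class <- "H"
  k <- plan$frequency * n
  if (any(abs(k - round(k)) > 1e-9)) {
    abort("infeasible frequency: frequency * n must be a whole number")
  }
  plan$k <- as.integer(round(k))
  withr::with_seed(seed, {
    chains <- list()
    for (cls in unique(plan$chain_class)) {
      ct <- if (cls == "H") "H" else "K"
      sub <- plan[plan$chain_class == cls, ]
      for (i in seq_len(n)) {
        cid <- sprintf("panel_%s%03d", cls, i)
        tmpl <- .fresh_template(128L)
        for (r in seq_len(nrow(sub))) {
          if (i > sub$k[r]) next
          res <- .plant_plan_row(tmpl, sub$motif_tag[r],
                                 imgt_start = sub$imgt_start[r])
          tmpl <- res$tmpl
        }
        chains[[length(chains) + 1L]] <- numbered_chain(
          cid, ct, seq_len(128L), tmpl$residues,
          v_call = "panel-V", j_call = "panel-J", species_label = "human")
      }
    }
    panel <- dplyr::bind_rows(chains)
    expected <- plan |>
      dplyr::mutate(imgt_start = as.character(.data$imgt_start),
                    count = .data$k, denominator = n,
                    frequency = .data$k / n) |>
      dplyr::filter(.data$count > 0L) |>
      dplyr::select("chain_class", "motif_tag", "imgt_start", "count",
                    "denominator", "frequency") |>
      dplyr::arrange(.data$chain_class, .data$motif_tag, .data$imgt_start)
    list(panel = panel, expected = expected)
  })
}

#' Generate a toy paired-Fv structure with known burial
#'
#' Places one pseudo-atom per residue on a widely spaced backbone (no
#' cross-residue occlusion) and surrounds residues designated buried with
#' a fully occluding dummy-atom shell, so the expected exposure classes
#' are exact.
#'
#' @param chains A paired unit's chain tibble (one H, one K/L).
#' @param buried Tibble of residues to bury: `chain_role` (`"H"`/`"L"`),
#'   `position` (IMGT label). All other residues are exposed.
#' @param seed Integer seed (controls small coordinate jitter).
#' @return `list(atoms, expected = tibble(chain_role, position,
#'   exposure_class))`.
#' @export
generate_toy_structure <- function(chains, buried = NULL, seed = 1L) {
  types <- unique(chains[, c("chain_id", "chain_type")])
  if (sum(types$chain_type == "H") != 1L ||
      sum(types$chain_type %in% c("K", "L")) != 1L) {
    abort("generate_toy_structure() needs one heavy and one light chain")
  }
  if (is.null(buried)) {
    buried <- tibble(chain_role = character(0), position = character(0))
  }
  withr::with_seed(seed, {
    shell <- fibonacci_sphere(60L) * 3
    atoms <- list()
    expected <- list()
    for (cid in types$chain_id) {
      chain <- chains[chains$chain_id == cid, ]
      role <- if (chain$chain_type[1] == "H") "H" else "L"
      y0 <- if (role == "H") 0 else 500
      for (i in seq_len(nrow(chain))) {
        lab <- imgt_label(chain$position[i], chain$insertion[i])
        cx <- 12 * i + stats::runif(1, -0.3, 0.3)
        cy <- y0 + stats::runif(1, -0.3, 0.3)
        cz <- stats::runif(1, -0.3, 0.3)
        atoms[[length(atoms) + 1L]] <- tibble(
          x = cx, y = cy, z = cz, element = "C", chain_role = role,
          position = lab, residue = chain$residue[i], occupancy = 1,
          mapped = TRUE)
        bury <- any(buried$chain_role == role & buried$position == lab)
        if (bury) {
          atoms[[length(atoms) + 1L]] <- tibble(
            x = cx + shell[, 1], y = cy + shell[, 2], z = cz + shell[, 3],
            element = "C", chain_role = NA_character_,
            position = NA_character_, residue = NA_character_,
            occupancy = 1, mapped = FALSE)
        }
        expected[[length(expected) + 1L]] <- tibble(
          chain_role = role, position = lab,
          exposure_class = if (bury) "buried" else "exposed")
      }
    }
    list(atoms = dplyr::bind_rows(atoms),
         expected = dplyr::bind_rows(expected))
  })
}

#' Generate benchmark modification records with a known effect direction
#'
#' Builds a small panel of profiled "therapeutics" whose liabilities carry
#' germline/therapeutic flags, and measured modification records where
#' flagged liabilities draw their percent modification from a
#' low-modification Beta distribution and unflagged ones from a high one,
#' plus oxidation indicators with the analogous bias.
#'
#' @param n_therapeutics Number of therapeutics.
#' @param seed Integer seed.
#' @param low_shape,high_shape Beta shape pairs for flagged / unflagged
#'   percent-modification draws (defaults mean 20% vs 80%).
#' @param training_fraction Fraction of therapeutics marked as therapeutic
#'   flag training-set members.
#' @return `list(records, profile)` where `profile` is a minimal
#'   `liab_profile` (hits + units).
#' @export
generate_benchmark_records <- function(n_therapeutics = 30L, seed = 1L,
                                       low_shape = c(2, 8),
                                       high_shape = c(8, 2),
                                       training_fraction = 0.2) {
  withr::with_seed(seed, {
    hits <- list()
    records <- list()
    training <- stats::runif(n_therapeutics) < training_fraction
    conds <- c("deamidation_high_pH", "deamidation_low_pH",
               "isomerization_low_pH")
    for (t in seq_len(n_therapeutics)) {
      tid <- sprintf("ther%03d", t)
      n_liab <- sample(2:4, 1L)
      for (j in seq_len(n_liab)) {
        tag <- sample(c("DeAmdH", "Isom", "MetOx"), 1L)
        pos <- as.character(sample(c(28:36, 57:63, 106:115), 1L))
        flag_g <- stats::runif(1) < 0.5
        flag_t <- stats::runif(1) < 0.3
        flagged <- flag_g || flag_t
        hits[[length(hits) + 1L]] <- tibble(
          chain_id = paste0(tid, "_H"), unit_id = tid, chain_type = "H",
          motif_tag = tag, imgt_start = pos, rule_kind = "motif_scan",
          germline = flag_g, therapeutic = flag_t,
          surface = NA_character_)
        cond <- if (tag == "MetOx") "oxidation" else sample(conds, 1L)
        value <- if (cond == "oxidation") {
          as.numeric(stats::runif(1) < (if (flagged) 0.2 else 0.8))
        } else {
          100 * (if (flagged) stats::rbeta(1, low_shape[1], low_shape[2])
                 else stats::rbeta(1, high_shape[1], high_shape[2]))
        }
        records[[length(records) + 1L]] <- tibble(
          therapeutic_id = tid, motif_tag = tag, imgt_start = pos,
          condition = cond, value = value,
          in_flag_training = training[t])
      }
    }
    hits <- dplyr::bind_rows(hits)
    units <- tibble(unit_id = unique(hits$unit_id))
    profile <- structure(list(hits = hits, units = units,
                              flags_applied = c("germline", "therapeutic")),
                         class = "liab_profile")
    list(records = dplyr::bind_rows(records), profile = profile)
  })
}

#' Generate random profiles with exactly controlled flag rates
#'
#' Produces a dataset of units with random liability counts whose flag
#' annotations are assigned to an exact fraction of hits — useful for
#' testing flag-reduction accounting (benign + non-benign = total,
#' monotonicity over combinations).
#'
#' @param n_units Number of units.
#' @param seed Integer seed.
#' @param mean_hits Poisson mean of liabilities per unit.
#' @param germline_rate,therapeutic_rate,buried_rate Fractions of hits
#'   flagged (exact counts, rounded down).
#' @return A minimal `liab_profile` with an attribute `rates` recording
#'   the exact flagged counts.
#' @export
synthetic_profiles <- function(n_units = 50L, seed = 1L, mean_hits = 3,
                               germline_rate = 0.4,
                               therapeutic_rate = 0.3,
                               buried_rate = 0.2) {
  withr::with_seed(seed, {
    n_hits_per <- stats::rpois(n_units, mean_hits)
    total <- sum(n_hits_per)
    uid <- rep(sprintf("u%04d", seq_len(n_units)), n_hits_per)
    hits <- tibble(
      chain_id = paste0(uid, "_H"), unit_id = uid, chain_type = "H",
      motif_tag = sample(c("DeAmdH", "Isom", "TrpOx", "MetOx", "FragM"),
                         total, replace = TRUE),
      imgt_start = as.character(sample(27:117, total, replace = TRUE)),
      rule_kind = "motif_scan",
      germline = FALSE, therapeutic = FALSE,
      surface = "exposed")
    ng <- floor(germline_rate * total)
    nt <- floor(therapeutic_rate * total)
    nb <- floor(buried_rate * total)
    hits$germline[sample(total, ng)] <- TRUE
    hits$therapeutic[sample(total, nt)] <- TRUE
    hits$surface[sample(total, nb)] <- "buried"
    units <- tibble(unit_id = sprintf("u%04d", seq_len(n_units)))
    structure(list(hits = hits, units = units,
                   flags_applied = c("germline", "therapeutic", "surface"),
                   rates = list(germline = ng, therapeutic = nt,
                                buried = nb, total = total)),
              class = "liab_profile")
  })
}
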