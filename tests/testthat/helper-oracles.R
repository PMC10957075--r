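# Independent oracles used across the suite. These deliberately avoid the
# package's own matching/integration code paths.

# Brute-force motif scan: slide every expanded k-mer over the residue
# string and apply the scope rule directly.
oracle_scan <- function(chains, ref = liability_reference(),
                        policy = "inclusive") {
  scan <- ref[ref$rule_kind == "motif_scan", ]
  rows <- list()
  for (cid in unique(chains$chain_id)) {
    chain <- chains[chains$chain_id == cid, ]
    res <- chain$residue
    n <- length(res)
    labels <- paste0(chain$position,
                     ifelse(is.na(chain$insertion), "", chain$insertion))
    in_cdr <- chain$position >= 27 & chain$position <= 38 |
      chain$position >= 56 & chain$position <= 65 |
      chain$position >= 105 & chain$position <= 117
    for (i in seq_len(nrow(scan))) {
      for (km in expand_pattern(scan$pattern[i])) {
        len <- nchar(km)
        kchars <- strsplit(km, "")[[1]]
        if (n < len) next
        ok <- rep(TRUE, n - len + 1L)
        for (j in seq_len(len)) {
          ok <- ok & res[j:(n - len + j)] == kchars[j]
        }
        for (st in which(ok)) {
          cover <- in_cdr[st:(st + len - 1L)]
          if (scan$scope[i] == "cdrs") {
            keep <- if (policy == "inclusive") any(cover) else all(cover)
            if (!keep) next
          }
          rows[[length(rows) + 1L]] <- data.frame(
            chain_id = cid, motif_tag = scan$tag[i],
            imgt_start = labels[st], matched = km,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chain_id = character(0), motif_tag = character(0),
                      imgt_start = character(0), matched = character(0)))
  }
  do.call(rbind, rows)
}

hit_keys <- function(df) {
  sort(paste(df$chain_id, df$motif_tag, df$imgt_start, df$matched,
             sep = "|"))
}

# Random chains over the full residue alphabet, with numbering gaps and
# occasional CDR3 insertion codes.
random_chains <- function(n, seed = 1) {
  withr::with_seed(seed, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      pos <- sort(sample(1:128, rbinom(1, 128, 0.92)))
      ins <- rep("", length(pos))
      if (runif(1) < 0.3 && 111 %in% pos) {
        at <- match(111, pos)
        pos <- append(pos, c(111L, 111L), after = at)
        ins <- append(ins, c("A", "B"), after = at)
      }
      res <- sample(abliab::aa_standard, length(pos), replace = TRUE)
      out[[k]] <- tibble::tibble(
        chain_id = sprintf("rnd%04d", k), chain_type = "H",
        position = as.integer(pos), insertion = ins, residue = res,
        v_call = "v", j_call = "j", species_label = "human",
        unit_id = NA_character_)
    }
    dplyr::bind_rows(out)
  })
}

# Numerical-integration SASA oracle at ~4x point density on a different
# deterministic lattice (equal-area z/phi grid).
oracle_sasa <- function(atoms, probe_radius = 1.4, nz = 62L, nphi = 62L) {
  z <- -1 + (2 * seq_len(nz) - 1) / nz
  phi <- 2 * pi * seq_len(nphi) / nphi
  g <- expand.grid(z = z, phi = phi)
  r <- sqrt(pmax(0, 1 - g$z^2))
  pts <- cbind(r * cos(g$phi), r * sin(g$phi), g$z)
  np <- nrow(pts)
  vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  rad <- unname(vdw[toupper(atoms$element)])
  rad[is.na(rad)] <- 1.70
  rad <- rad + probe_radius
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(atoms)
  area <- numeric(n)
  for (i in seq_len(n)) {
    if (!atoms$mapped[i]) next
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, np)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & d2 >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / np
  }
  res <- atoms[atoms$mapped, , drop = FALSE]
  res$abs_sasa_oracle <- area[atoms$mapped]
  stats::aggregate(abs_sasa_oracle ~ chain_role + position, data = res, sum)
}

# Exhaustive hypergeometric enumeration for a 2x2 table via choose(),
# independent of dhyper.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; k <- a + c_; n_tot <- a + b + c_ + d
  lo <- max(0, k - (n_tot - m)); hi <- min(k, m)
  pr <- function(x) {
    exp(lchoose(m, x) + lchoose(n_tot - m, k - x) - lchoose(n_tot, k))
  }
  probs <- vapply(lo:hi, pr, 1)
  sum(probs[probs <= pr(a) * (1 + 1e-7)])
}
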