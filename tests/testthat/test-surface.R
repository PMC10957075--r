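test_that("an isolated residue is nearly fully accessible", {
  atoms <- tibble::tibble(x = 0, y = 0, z = 0, element = "C",
                          chain_role = "H", position = "1",
                          residue = "A", occupancy = 1, mapped = TRUE)
  ex <- residue_exposure(atoms)
  expect_equal(ex$rel_sasa, 1, tolerance = 0.10)
  expect_equal(ex$exposure_class, "exposed")
  # a lone sphere's SASA is exact: 4*pi*(1.7+1.4)^2
  expect_equal(ex$abs_sasa, 4 * pi * 3.1^2, tolerance = 1e-10)
})

test_that("a residue enclosed by a dense 3-Angstrom shell has zero SASA", {
  shell <- abliab:::fibonacci_sphere(60L) * 3
  atoms <- dplyr::bind_rows(
    tibble::tibble(x = 0, y = 0, z = 0, element = "C", chain_role = "H",
                   position = "1", residue = "A", occupancy = 1,
                   mapped = TRUE),
    tibble::tibble(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                   element = "C", chain_role = NA, position = NA,
                   residue = NA, occupancy = 1, mapped = FALSE))
  sasa <- compute_sasa(atoms)
  expect_equal(sasa$abs_sasa, 0)
})

test_that("SASA matches a higher-density integration oracle within 2%", {
  withr::with_seed(77, {
    for (k in 1:8) {
      n_at <- sample(5:12, 1)
      atoms <- tibble::tibble(
        x = runif(n_at, 0, 6), y = runif(n_at, 0, 6), z = runif(n_at, 0, 6),
        element = sample(c("C", "N", "O", "S"), n_at, replace = TRUE),
        chain_role = "H", position = as.character(seq_len(n_at)),
        residue = "A", occupancy = 1, mapped = TRUE)
      got <- compute_sasa(atoms)
      want <- oracle_sasa(atoms)
      m <- merge(got, want, by = c("chain_role", "position"))
      # tolerance: 2% of the atom's full sphere area
      full <- 4 * pi * 3.4^2
      expect_true(all(abs(m$abs_sasa - m$abs_sasa_oracle) <= 0.02 * full),
                  label = paste("structure", k))
    }
  })
})

test_that("total SASA is the sum of per-residue SASA", {
  atoms <- tibble::tibble(
    x = c(0, 3, 6), y = 0, z = 0, element = "C", chain_role = "H",
    position = c("1", "2", "3"), residue = "A", occupancy = 1,
    mapped = TRUE)
  per <- compute_sasa(atoms)
  pooled <- atoms
  pooled$position <- "all"
  one <- compute_sasa(pooled)
  expect_equal(sum(per$abs_sasa), one$abs_sasa, tolerance = 1e-10)
})

test_that("classification is invariant under rigid-body motion", {
  unit <- generate_paired_units(1, seed = 78)
  st <- generate_toy_structure(
    unit$chains,
    buried = tibble::tibble(chain_role = "H",
                            position = as.character(40:44)),
    seed = 79)
  ex0 <- residue_exposure(st$atoms)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")]) %*% rot
  moved <- st$atoms
  moved$x <- xyz[, 1] + 100; moved$y <- xyz[, 2] - 50; moved$z <- xyz[, 3]
  ex1 <- residue_exposure(moved)
  expect_equal(ex1$exposure_class, ex0$exposure_class)
  expect_equal(ex1$abs_sasa, ex0$abs_sasa, tolerance = 1e-6)
})

test_that("exposure classification is strict at the 7.5% threshold", {
  expect_equal(classify_exposure(c(0, 0.075, 0.076, 0.5)),
               c("buried", "buried", "exposed", "exposed"))
  expect_error(classify_exposure(-0.1), "non-negative")
})

test_that("interface occlusion: isolated-chain SASA >= complex SASA", {
  # two chains brought into contact: pack the L chain next to the H chain
  h <- tibble::tibble(
    x = seq(0, 12, by = 4), y = 0, z = 0, element = "C", chain_role = "H",
    position = as.character(1:4), residue = "A", occupancy = 1,
    mapped = TRUE)
  l <- h
  l$chain_role <- "L"
  l$y <- 3.5
  complex_sasa <- compute_sasa(dplyr::bind_rows(h, l))
  iso <- compute_sasa(h)
  m <- merge(iso, complex_sasa[complex_sasa$chain_role == "H", ],
             by = "position")
  expect_true(all(m$abs_sasa.x >= m$abs_sasa.y - 1e-9))
  expect_true(any(m$abs_sasa.x > m$abs_sasa.y + 1))
})

test_that("surface flag summarises per-residue classes over the motif", {
  exposures <- tibble::tibble(
    chain_role = "H", position = c("30", "31", "40", "41"),
    residue = "A", abs_sasa = c(2, 3, 2, 40),
    rel_sasa = c(0.02, 0.03, 0.02, 0.30),
    exposure_class = c("buried", "buried", "buried", "exposed"))
  hits <- tibble::tibble(
    chain_id = "c", chain_type = "H",
    motif_tag = c("DeAmdH", "Isom", "mCys", "DeAmdH"),
    positions = list(c("30", "31"), c("40", "41"), character(0),
                     c("90", "91")),
    imgt_start = c("30", "40", "104", "90"),
    rule_kind = c("motif_scan", "motif_scan", "conserved_cys_missing",
                  "motif_scan"))
  expect_equal(flag_surface(hits, exposures),
               c("buried", "partial", "unknown", "unknown"))
})

test_that("PDB structures round-trip through bio3d for the SASA path", {
  unit <- generate_paired_units(1, seed = 80)
  st <- generate_toy_structure(
    unit$chains,
    buried = tibble::tibble(chain_role = "L", position = "60"),
    seed = 81)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  write_fv_structure(st$atoms, pdb)
  back <- read_fv_structure(pdb)
  expect_equal(nrow(back), nrow(st$atoms))
  expect_equal(sum(back$mapped), sum(st$atoms$mapped))
  ex <- residue_exposure(back)
  cmp <- dplyr::left_join(st$expected, ex, by = c("chain_role", "position"))
  expect_equal(cmp$exposure_class.y, cmp$exposure_class.x)
})
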