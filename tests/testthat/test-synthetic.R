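test_that("generators are deterministic in the seed", {
  g1 <- make_toy_germline_set(3)
  g2 <- make_toy_germline_set(3)
  expect_equal(g1, g2)
  expect_false(identical(make_toy_germline_set(4)$segments, g1$segments))

  c1 <- generate_chains(5, seed = 101, germline = g1)
  c2 <- generate_chains(5, seed = 101, germline = g1)
  expect_equal(c1, c2)
})

test_that("toy germline segments have conserved cysteines and exact ledgers", {
  germ <- make_toy_germline_set(1)
  v <- germ$segments[germ$segments$segment_type == "V", ]
  for (name in unique(v$chain_id)) {
    seg <- v[v$chain_id == name, ]
    expect_equal(seg$residue[seg$position == 23], "C", label = name)
    expect_equal(seg$residue[seg$position == 104], "C", label = name)
  }
  # the ledger is exactly what scanning recovers
  hits <- scan_chains(germ$segments)
  expect_identical(
    sort(paste(hits$chain_id, hits$motif_tag, hits$imgt_start)),
    sort(paste(germ$ledger$segment, germ$ledger$motif_tag,
               germ$ledger$imgt_start)))
  # >= 3 heavy subgroups
  subgroups <- unique(sub("-.*", "", unique(v$chain_id[v$chain_type == "H"])))
  expect_gte(length(subgroups), 3L)
})

test_that("planted chains reproduce the ledger through the scanner", {
  plan <- tibble::tibble(motif_tag = c("DeAmdH", "Isom", "FragM"),
                         region = c("CDR1", "CDR2", "CDR2"))
  gen <- generate_chains(10, plan, seed = 102)
  hits <- scan_chains(gen$chains)
  expect_equal(nrow(hits), 30L)
  expect_identical(
    sort(paste(hits$chain_id, hits$motif_tag, hits$imgt_start)),
    sort(paste(gen$ledger$chain_id, gen$ledger$motif_tag,
               gen$ledger$imgt_start)))
  # empty plan with germline: only germline-inherited motifs
  germ <- make_toy_germline_set(1)
  gen2 <- generate_chains(5, seed = 103, germline = germ)
  expect_true(all(gen2$ledger$origin == "germline"))
  hits2 <- scan_chains(gen2$chains)
  expect_equal(nrow(hits2), nrow(gen2$ledger))
})

test_that("boundary planting yields boundary attribution", {
  gen <- generate_chains(
    3, tibble::tibble(motif_tag = "DeAmdH", imgt_start = "38"), seed = 104)
  expect_true(all(gen$ledger$attribution == "boundary"))
  hits <- scan_chains(gen$chains)
  expect_true(all(hits$attribution == "boundary"))
  expect_true(all(hits$imgt_start == "38"))
})

test_that("cysteine anomalies can be planted", {
  gen <- generate_chains(
    2, tibble::tibble(motif_tag = c("mCys", "xCys"),
                      imgt_start = c("104", "35")), seed = 105)
  hits <- check_conserved_cysteines(gen$chains)
  expect_equal(sort(unique(hits$motif_tag)), c("mCys", "xCys"))
  expect_equal(nrow(hits), 4L)
})

test_that("unsatisfiable plans raise errors naming the motif", {
  expect_error(
    generate_chains(1, tibble::tibble(motif_tag = "DeAmdH",
                                      region = "CDR1", count = 20L),
                    seed = 106),
    "DeAmdH")
  expect_error(
    generate_therapeutic_panel(
      tibble::tibble(motif_tag = "DeAmdH", imgt_start = "57",
                     frequency = 1 / 3), 20, seed = 107),
    "infeasible")
  expect_error(
    generate_therapeutic_panel(
      tibble::tibble(motif_tag = "DeAmdH", imgt_start = "57",
                     frequency = 0.1), 0, seed = 108),
    ">= 1")
})

test_that("panel frequencies are exact and respect the strict threshold", {
  plan <- tibble::tibble(motif_tag = c("DeAmdH", "Isom"),
                         imgt_start = c("57", "30"),
                         frequency = c(0.05, 0.10))
  pan <- generate_therapeutic_panel(plan, 20, seed = 109)
  tab <- build_therapeutic_table(pan$panel)
  expect_equal(
    as.data.frame(tab[, c("chain_class", "motif_tag", "imgt_start",
                          "count", "frequency")]),
    as.data.frame(pan$expected[, c("chain_class", "motif_tag",
                                   "imgt_start", "count", "frequency")]))
  hits <- tibble::tibble(chain_id = "q", chain_type = "H",
                         motif_tag = c("DeAmdH", "Isom"),
                         imgt_start = c("57", "30"),
                         rule_kind = "motif_scan")
  expect_identical(flag_therapeutic(hits, tab), c(FALSE, TRUE))
})

test_that("toy structures reproduce their burial plan", {
  unit <- generate_paired_units(1, seed = 110)
  buried <- tibble::tibble(
    chain_role = c("H", "H", "L"), position = c("30", "57", "90"))
  st <- generate_toy_structure(unit$chains, buried, seed = 111)
  ex <- residue_exposure(st$atoms)
  cmp <- dplyr::left_join(st$expected, ex, by = c("chain_role", "position"))
  expect_false(any(is.na(cmp$exposure_class.y)))
  expect_equal(cmp$exposure_class.y, cmp$exposure_class.x)
})

test_that("full pipeline closure: generate, QC, scan, flag, summarize", {
  germ <- make_toy_germline_set(2)
  plan <- tibble::tibble(motif_tag = c("DeAmdH", "MetOx"),
                         region = c("CDR2", "CDR3"))
  gen <- generate_paired_units(6, plan_h = plan, plan_l = plan,
                               seed = 112, germline = germ)
  qc <- qc_filter(gen$chains, paired = TRUE)
  expect_equal(nrow(qc$ledger), 0L)
  tabpan <- generate_therapeutic_panel(
    tibble::tibble(motif_tag = "DeAmdH", imgt_start = "57",
                   frequency = 0.2), 10, seed = 113)
  tab <- build_therapeutic_table(tabpan$panel)
  prof <- profile_antibody(qc$kept, flags = c("germline", "therapeutic"),
                           germline = germ$segments,
                           therapeutic_table = tab)
  expect_equal(nrow(prof$hits), nrow(gen$ledger))
  expect_equal(sum(!is.na(prof$hits$germline) & prof$hits$germline),
               sum(gen$ledger$origin == "germline"))
  s <- summarize_dataset(prof)
  expect_equal(s$overview$total_liabilities, nrow(gen$ledger))
  expect_equal(s$overview$n_units, 6L)
  expect_equal(s$combos$remaining_liabilities[s$combos$combo == "germline"],
               sum(gen$ledger$origin == "planted"))
})
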