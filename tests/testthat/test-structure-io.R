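test_that("minimal mmCIF parses atoms and the unobserved-residue loop", {
  m <- parse_structure(mini_cif())
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 2)
  expect_equal(nrow(m$unobserved), 1)
  expect_equal(m$unobserved$resid, 2L)
  expect_equal(m$structure_id, "MINI")

  no_loop <- parse_structure(mini_cif(with_unobs = FALSE))
  expect_equal(nrow(no_loop$unobserved), 0)
})

test_that("malformed input raises parse errors naming the problem", {
  broken <- sub("ATOM 1 C CA . ALA A 1 0.000 0.000 0.000 1.00 1",
                "ATOM 1 C CA . ALA A 1 0.000 0.000", mini_cif())
  expect_error(parse_structure(broken), "_atom_site")
  expect_error(parse_structure("data_EMPTY\n#\n"), "atom_site")
})

test_that("altloc duplicates resolve to highest occupancy, ties alphabetical", {
  txt <- paste(c(
    "data_ALT", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy",
    "ATOM 1 C CA A ALA A 1 1.0 0.0 0.0 0.40",
    "ATOM 2 C CA B ALA A 1 2.0 0.0 0.0 0.60",
    "ATOM 3 C CA A ALA A 2 5.0 0.0 0.0 0.50",
    "ATOM 4 C CA B ALA A 2 6.0 0.0 0.0 0.50", "#"), collapse = "\n")
  m <- parse_structure(txt)
  expect_equal(nrow(m$atoms), 2)
  expect_equal(m$atoms$x, c(2.0, 5.0))    # occupancy winner, then altloc A
})

test_that("consecutive unobserved residues merge into maximal flanked regions", {
  obs <- setdiff(1:20, 10:14)
  coords <- cbind(seq_along(obs) * 3.8, 0, 0)
  un <- data.frame(chain = "A", resid = 10:14, resname = "GLY",
                   zero_occ = FALSE)
  m <- make_ca_model(coords, resid = obs, unobserved = un)
  r <- extract_missing_regions(m)
  expect_equal(nrow(r), 1)
  expect_equal(r$length, 5L)
  expect_equal(c(r$left_flank, r$right_flank), c(9L, 15L))
})

test_that("terminal runs get an absent flank and are ineligible", {
  obs <- 5:12
  coords <- cbind(seq_along(obs) * 3.8, 0, 0)
  un <- data.frame(chain = "A", resid = 1:4, resname = "GLY", zero_occ = FALSE)
  m <- make_ca_model(coords, resid = obs, unobserved = un)
  r <- flank_distance(m)
  expect_equal(nrow(r), 1)
  expect_true(is.na(r$left_flank))
  expect_false(r$eligible)
  expect_true(is.na(r$distance))
})

test_that("gaps in different chains stay chain-segregated", {
  a <- make_ca_model(cbind(1:8 * 3.8, 0, 0), chain = "A", resid = setdiff(1:10, 4:5))
  b <- make_ca_model(cbind(1:8 * 3.8, 0, 10), chain = "B", resid = setdiff(1:10, 7:8))
  un <- data.frame(chain = c("A", "A", "B", "B"), resid = c(4L, 5L, 7L, 8L),
                   resname = "GLY", zero_occ = FALSE)
  m <- structure_model("TWO", rbind(a$atoms, b$atoms), un)
  r <- extract_missing_regions(m)
  expect_equal(nrow(r), 2)
  expect_setequal(r$chain, c("A", "B"))
})

test_that("flank distance follows plain Euclidean geometry", {
  un <- data.frame(chain = "A", resid = 2L, resname = "GLY", zero_occ = FALSE)
  m345 <- make_ca_model(rbind(c(0, 0, 0), c(3, 4, 0)), resid = c(1L, 3L),
                        unobserved = un)
  expect_equal(flank_distance(m345)$distance, 5.0)

  coincident <- make_ca_model(rbind(c(1, 1, 1), c(1, 1, 1)), resid = c(1L, 3L),
                              unobserved = un)
  expect_equal(flank_distance(coincident)$distance, 0.0)
})

test_that("a fully observed structure yields zero regions", {
  m <- make_ca_model(cbind(1:10 * 3.8, 0, 0))
  expect_equal(nrow(extract_missing_regions(m)), 0)
})

test_that("region lengths partition the unobserved residue count", {
  for (seed in c(2, 7, 19)) {
    g <- gen_structure(seed = seed, n_residues = 150, n_gaps = 3)
    m <- parse_structure(g$text)
    r <- extract_missing_regions(m)
    expect_equal(sum(r$length), nrow(m$unobserved))
  }
})

test_that("generator fixtures round-trip to the ledger ground truth", {
  g <- gen_structure(seed = 7, n_gaps = 2)
  m <- parse_structure(g$text)
  r <- flank_distance(m)
  expect_equal(r$start, g$ledger$start)
  expect_equal(r$end, g$ledger$end)
  expect_equal(r$left_flank, g$ledger$left_flank)
  expect_equal(r$right_flank, g$ledger$right_flank)
  expect_lt(max(abs(r$distance - g$ledger$distance)), 1e-9)
})

test_that("flank distances are invariant under global rigid motion", {
  set.seed(42)
  g <- gen_structure(seed = 13, n_residues = 100, n_gaps = 2)
  r0 <- region_distances(g$model)
  moved <- rigidly_move(g$model, random_rotation(), c(10, -4, 2))
  r1 <- region_distances(moved)
  expect_equal(r1$distance, r0$distance, tolerance = 1e-9)
})

test_that("mmCIF writer output reparses to the identical model", {
  g <- gen_structure(seed = 3, n_residues = 60, n_gaps = 1)
  m1 <- parse_structure(write_mmcif(g$model))
  expect_equal(m1$atoms$resid, g$model$atoms$resid)
  expect_equal(m1$atoms[, c("x", "y", "z")], g$model$atoms[, c("x", "y", "z")])
  expect_equal(m1$unobserved$resid, g$model$unobserved$resid)
})
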