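toy_ledger <- function(rows) {
  paste(c("ProteinA\tResA\tProteinB\tResB\tReplicate", rows), collapse = "\n")
}

test_that("ledger loading deduplicates unordered residue pairs", {
  led <- load_ledger(toy_ledger(c("E1o\t10\tE1o\t50\trep1",
                                  "E1o\t50\tE1o\t10\trep2",
                                  "E1o\t10\tE2o\t7\trep1")))
  expect_equal(nrow(led), 2)
  expect_equal(sort(led$link_type), c("inter", "intra"))
  dup <- led[led$link_type == "intra", ]
  expect_equal(dup$n_obs, 2L)
  expect_equal(dup$replicates, "rep1;rep2")
})

test_that("self pairs and unparseable rows are skipped with a message", {
  expect_message(
    led <- load_ledger(toy_ledger(c("A\t5\tA\t5\trep1",
                                    "A\tx\tB\t9\trep1",
                                    "A\t5\tB\t9\trep1"))),
    "skipped")
  expect_equal(nrow(led), 1)
})

test_that("a missing mandatory column is reported by name", {
  bad <- paste(c("ProteinA\tResA\tProteinB\tReplicate", "A\t1\tB\tr"),
               collapse = "\n")
  expect_error(load_ledger(bad), "res_b")
})

test_that("generated ledgers round-trip losslessly", {
  g <- gen_structure(seed = 11, n_residues = 150)
  xl <- gen_crosslinks(g$model, n_links = 120, frac_satisfied = 0.75, seed = 11)
  txt <- paste(capture.output(write.table(xl$table, sep = "\t", quote = FALSE,
                                          row.names = FALSE)), collapse = "\n")
  led <- load_ledger(txt)
  expect_equal(nrow(led), nrow(xl$table))
})

test_that("link mapping measures Calpha distances and honours the minimum rule", {
  m <- make_ca_model(rbind(c(0, 0, 0), c(8, 0, 0)), resid = c(1L, 2L))
  rec <- data.frame(protein_a = "P", res_a = 1L, protein_b = "P", res_b = 2L,
                    link_type = "intra")
  mp <- map_links(m, rec, list(P = "A"))
  expect_equal(mp$distance, 8)

  # homodimer: intra-chain 40 A but cross-chain 12 A
  dimer <- make_two_chain_model(rbind(c(0, 0, 0), c(40, 0, 0)),
                                rbind(c(100, 100, 100), c(12, 0, 0)))
  mp2 <- map_links(dimer, rec, list(P = c("A", "B")))
  expect_equal(mp2$distance, 12)
})

test_that("mapped distances reproduce the generator ground truth", {
  g <- gen_structure(seed = 11, n_residues = 150)
  xl <- gen_crosslinks(g$model, n_links = 150, frac_satisfied = 0.7,
                       decoy_rate = 0.1, seed = 4)
  led <- data.frame(protein_a = xl$table$ProteinA, res_a = xl$table$ResA,
                    protein_b = xl$table$ProteinB, res_b = xl$table$ResB,
                    link_type = "intra")
  mp <- map_links(g$model, led, xl$chain_map)
  mapped <- !xl$truth$decoy
  expect_equal(mp$distance[mapped], xl$truth$distance[mapped], tolerance = 1e-9)
  expect_true(all(is.na(mp$distance[!mapped])))
})

test_that("mapping is invariant under endpoint swap and rigid motion", {
  set.seed(21)
  g <- gen_structure(seed = 21, n_residues = 80)
  rec <- data.frame(protein_a = "SYN1", res_a = c(3L, 10L),
                    protein_b = "SYN1", res_b = c(40L, 62L),
                    link_type = "intra")
  swapped <- data.frame(protein_a = rec$protein_b, res_a = rec$res_b,
                        protein_b = rec$protein_a, res_b = rec$res_a,
                        link_type = "intra")
  cm <- list(SYN1 = "A")
  expect_equal(map_links(g$model, rec, cm)$distance,
               map_links(g$model, swapped, cm)$distance)
  moved <- rigidly_move(g$model, random_rotation(), c(3, 1, -9))
  expect_equal(map_links(moved, rec, cm)$distance,
               map_links(g$model, rec, cm)$distance, tolerance = 1e-9)
})

test_that("satisfaction counts are inclusive at the cutoff and monotone", {
  mp <- data.frame(distance = c(10, 20, 30, NA))
  expect_equal(satisfaction(mp, 30)$fraction, 1)
  expect_equal(satisfaction(mp, 29.999)$fraction, 2 / 3)
  expect_equal(satisfaction(mp, 30)$n_unmapped, 1)
  thr <- seq(5, 60, by = 5)
  prof <- satisfaction_profile(mp, thr)
  expect_true(all(diff(prof$fraction) >= 0))
  expect_equal(prof$fraction[length(thr)], 1)
  expect_error(satisfaction(data.frame(distance = NA_real_), 30), "no mapped")
})

test_that("planted satisfied fractions are recovered exactly", {
  g <- gen_structure(seed = 5, n_residues = 150)
  for (f in c(0.5, 0.8, 1.0)) {
    xl <- gen_crosslinks(g$model, n_links = 100, frac_satisfied = f,
                         threshold = 30, seed = 6)
    rec <- data.frame(protein_a = xl$table$ProteinA, res_a = xl$table$ResA,
                      protein_b = xl$table$ProteinB, res_b = xl$table$ResB,
                      link_type = "intra")
    mp <- map_links(g$model, rec, xl$chain_map)
    expect_equal(satisfaction(mp, 30)$fraction, f)
  }
})

test_that("satisfaction equals a direct count oracle on generated links", {
  g <- gen_structure(seed = 8, n_residues = 150)
  xl <- gen_crosslinks(g$model, n_links = 200, frac_satisfied = 0.65, seed = 9)
  rec <- data.frame(protein_a = xl$table$ProteinA, res_a = xl$table$ResA,
                    protein_b = xl$table$ProteinB, res_b = xl$table$ResB,
                    link_type = "intra")
  mp <- map_links(g$model, rec, xl$chain_map)
  expect_equal(satisfaction(mp, 30)$fraction,
               sum(mp$distance <= 30) / nrow(mp))
})

test_that("log-normal MLE recovers generating parameters", {
  set.seed(1)
  d <- rlnorm(2000, meanlog = 3.0, sdlog = 0.4)
  f <- fit_distance_distribution(d)
  expect_lt(abs(f$mu - 3.0) / 3.0, 0.05)
  expect_lt(abs(f$sigma - 0.4) / 0.4, 0.05)
  expect_error(fit_distance_distribution(rep(7, 10)), "degenerate")
  expect_error(fit_distance_distribution(c(-1, 2, 3, 4, 5)), "positive")
  expect_error(fit_distance_distribution(c(1, 2, 3)), "at least 5")
})

test_that("MLE agrees with an independent distribution-fitting routine", {
  skip_if_not_installed("fitdistrplus")
  set.seed(2)
  d <- rlnorm(500, 2.5, 0.3)
  f <- fit_distance_distribution(d)
  ref <- fitdistrplus::fitdist(d, "lnorm")
  expect_equal(f$mu, unname(ref$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(f$sigma, unname(ref$estimate["sdlog"]), tolerance = 1e-3)
})

test_that("the log-normal fit beats a mis-specified normal on KS distance", {
  set.seed(3)
  d <- rlnorm(1000, 3.0, 0.4)
  f <- fit_distance_distribution(d)
  ks_norm <- suppressWarnings(
    stats::ks.test(d, "pnorm", mean = mean(d), sd = sd(d))$statistic)
  expect_lt(f$ks_stat, unname(ks_norm))
})

test_that("link summaries count unique intra and inter links", {
  led <- load_ledger(toy_ledger(c("A\t1\tA\t9\trep1",
                                  "A\t9\tA\t1\trep2",
                                  "A\t2\tB\t3\trep1")))
  s <- link_summary(led)
  expect_equal(s$intra$n[s$intra$protein == "A"], 1)
  expect_equal(s$inter$n, 1)
  expect_equal(s$totals$n_intra + s$totals$n_inter, s$totals$n_unique)

  restricted <- link_summary(led, proteins = c("A", "B"))
  expect_equal(restricted$totals, s$totals)
  only_a <- link_summary(led, proteins = "A")
  expect_equal(only_a$totals$n_inter, 0)
})

test_that("planted per-protein counts are recovered exactly", {
  rows <- c(sprintf("E1o\t%d\tE1o\t%d\trep1", 1:12, 101:112),
            sprintf("E2o\t%d\tE2o\t%d\trep1", 1:7, 201:207),
            sprintf("E1o\t%d\tE3\t%d\trep1", 1:5, 301:305))
  s <- link_summary(load_ledger(toy_ledger(rows)))
  expect_equal(s$intra$n[s$intra$protein == "E1o"], 12)
  expect_equal(s$intra$n[s$intra$protein == "E2o"], 7)
  expect_equal(s$inter$n[s$inter$protein_a == "E1o" & s$inter$protein_b == "E3"], 5)
  expect_equal(s$totals$n_unique, 24)
})
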