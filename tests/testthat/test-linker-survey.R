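test_that("the adaptive bin scheme matches the published edges", {
  sc <- build_bins()
  expect_equal(sc$edges[1:50], 1:50)
  expect_equal(sc$edges[51:60], c(55, 60, 65, 70, 75, 100, 125, 150, 250, 4000))
  expect_equal(sc$left[3], 3L)                       # unit bin [3,3]
  expect_equal(assign_bins(3, sc), 3L)
  expect_equal(c(sc$left[assign_bins(52, sc)], sc$right[assign_bins(52, sc)]),
               c(51L, 55L))                          # (50,55]
  i <- assign_bins(3736, sc)
  expect_equal(c(sc$left[i], sc$right[i]), c(251L, 4000L))
  expect_error(assign_bins(4001, sc), "4000")
})

test_that("bin membership is a partition of 1..4000", {
  sc <- build_bins()
  idx <- assign_bins(1:4000, sc)
  expect_true(all(idx >= 1 & idx <= length(sc$edges)))
  expect_true(all(1:4000 > c(0, sc$edges)[idx] & 1:4000 <= sc$edges[idx]))
})

test_that("bin summaries reduce correctly on tiny inputs", {
  rec1 <- data.frame(length = 10L, distance = 12, eligible = TRUE)
  s1 <- summarize_survey(rec1)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$mean_distance, 12)
  expect_equal(unlist(s1[sprintf("q%.1f", seq(0, 1, 0.2))], use.names = FALSE),
               rep(12, 6))

  rec3 <- data.frame(length = c(20L, 20L, 20L), distance = c(4, 6, 8),
                     eligible = TRUE)
  s3 <- summarize_survey(rec3)
  expect_equal(s3$mean_distance, 6)
  expect_equal(s3$`q0.0`, 4)
  expect_equal(s3$`q1.0`, 8)
})

test_that("large random surveys agree with a naive per-bin loop oracle", {
  set.seed(11)
  n <- 10000
  lengths <- sample(1:300, n, replace = TRUE, prob = 1 / (1:300))
  rec <- data.frame(length = lengths,
                    distance = abs(rnorm(n, 10, 4)) + 0.1, eligible = TRUE)
  sc <- build_bins()
  s <- summarize_survey(rec, sc)
  o <- naive_bin_summary(rec$length, rec$distance, sc$edges)
  expect_equal(nrow(s), nrow(o))
  expect_equal(s$n, unname(o[, "n"]))
  expect_lt(max(abs(s$mean_distance - o[, "mean"])), 1e-9)
  for (q in sprintf("q%.1f", seq(0, 1, 0.2)))
    expect_lt(max(abs(s[[q]] - o[, q])), 1e-9)
  expect_equal(sum(s$n), n)      # partition invariant
})

test_that("noiseless surveys recover the generating constants to 1e-6", {
  sp <- gen_survey_points(A = 11, b = 0.2, noise_sd = 0, seed = 1)
  f <- fit_saturation(sp)
  expect_equal(f$A, 11, tolerance = 1e-6)
  expect_equal(f$b, 0.2, tolerance = 1e-6)
  expect_lt(f$residual_ss, 1e-12)
})

test_that("a flat survey at the offset is degenerate with A = 0", {
  flat <- data.frame(bin_mid = c(5, 15, 30, 60), mean_distance = rep(3.5, 4))
  f <- fit_saturation(flat)
  expect_equal(f$A, 0)
  expect_true(f$degenerate)
  expect_true(is.na(f$b))
})

test_that("the nonlinear fit lands on the grid-search minimizer", {
  sp <- gen_survey_points(A = 11, b = 0.2, noise_sd = 0.3, seed = 3)
  f <- fit_saturation(sp)
  g <- grid_fit_saturation(sp$bin_mid, sp$mean_distance,
                           A_grid = seq(10, 12, by = 0.02),
                           b_grid = seq(0.15, 0.25, by = 0.002))
  expect_lt(abs(f$A - g$A), 0.02 + 1e-9)
  expect_lt(abs(f$b - g$b), 0.002 + 1e-9)
  expect_lte(f$residual_ss, g$ss + 1e-9)
})

test_that("parameter recovery holds at survey noise levels", {
  sp <- gen_survey_points(A = 11, b = 0.2, noise_sd = 0.3, seed = 17)
  expect_gte(nrow(sp), 40)
  f <- fit_saturation(sp)
  expect_lt(abs(f$A - 11) / 11, 0.05)
  expect_lt(abs(f$b - 0.2) / 0.2, 0.10)
})

test_that("model evaluation honours its analytic anchors", {
  fit <- structure(list(A = 11, b = 0.2, offset = 3.5, degenerate = FALSE),
                   class = "saturation_fit")
  expect_identical(evaluate_model(fit, 0), 3.5)
  expect_equal(evaluate_model(fit, 10000), 14.5, tolerance = 1e-9)
  y <- evaluate_model(fit, 0:500)
  expect_true(all(diff(y) >= 0))
  expect_true(all(y >= 3.5 & y <= 11 + 3.5))
})

test_that("theoretical reference curves follow their stated forms", {
  ext <- theoretical_curve("extended_perres", lengths = 10)
  expect_equal(ext$values$distance, 70)
  for (m in c("marsh_formankay", "wilkins", "george_heringa")) {
    tc <- theoretical_curve(m, lengths = 1)
    expect_equal(tc$values$distance, tc$constants$prefactor)
  }
  expect_error(theoretical_curve("nope"), "supported")
  # comparison table at the 73-residue linker length of the tether arm
  tab <- sapply(c("extended_perres", "marsh_formankay", "wilkins",
                  "george_heringa"),
                function(m) theoretical_curve(m, lengths = 73)$values$distance)
  expect_true(all(tab > 0))
  expect_equal(unname(tab["extended_perres"]), 7 * 73)
  custom <- theoretical_curve("wilkins", lengths = 73,
                              constants = list(prefactor = 3))
  expect_equal(custom$values$distance, 3 * 73^0.57)
})

test_that("curves are monotone non-decreasing for shipped defaults", {
  for (m in c("extended_perres", "marsh_formankay", "wilkins", "george_heringa")) {
    v <- theoretical_curve(m, lengths = 1:200)$values$distance
    expect_true(all(diff(v) >= 0))
  }
})
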