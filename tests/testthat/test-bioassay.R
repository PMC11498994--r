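test_that("standard curves reproduce exact and noisy least squares", {
  conc <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  exact <- fit_standard_curve(conc, 2 * conc + 0.1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 0.1)
  expect_equal(exact$r_squared, 1)
  two <- fit_standard_curve(c(1, 3), c(0.2, 0.8))
  expect_equal(two$slope, 0.3)
  expect_equal(two$intercept, -0.1)
  set.seed(4)
  a <- 2 * conc + 0.1 + rnorm(5, sd = 0.01)
  noisy <- fit_standard_curve(conc, a)
  oracle <- ols_normal_equations(conc, a)
  expect_equal(noisy$intercept, unname(oracle[1L]), tolerance = 1e-10)
  expect_equal(noisy$slope, unname(oracle[2L]), tolerance = 1e-10)
  expect_error(fit_standard_curve(c(1, 1), c(1, 2)), "distinct")
})

test_that("DPPH scavenging follows the blank-corrected formula", {
  expect_equal(dpph_scavenging_rate(0.4, 0.4, 0.7), 100)
  expect_equal(dpph_scavenging_rate(0.9, 0.2, 0.7), 0)
  expect_equal(dpph_scavenging_rate(0.5, 0.1, 0.8), 50)
  # affine in a_sample (decreasing), increasing in a_control
  expect_lt(dpph_scavenging_rate(0.6, 0.1, 0.8),
            dpph_scavenging_rate(0.5, 0.1, 0.8))
  expect_gt(dpph_scavenging_rate(0.5, 0.2, 0.8),
            dpph_scavenging_rate(0.5, 0.1, 0.8))
  # invariant under common rescaling of all three absorbances
  expect_equal(dpph_scavenging_rate(1.5, 0.3, 2.4),
               dpph_scavenging_rate(0.5, 0.1, 0.8))
  expect_warning(dpph_scavenging_rate(1.4, 0.1, 0.8), "outside")
  expect_error(dpph_scavenging_rate(0.5, 0.1, 0), "positive")
})

test_that("scavenging rates round-trip through simulated absorbances", {
  a_std <- 0.83; a_ctrl <- 0.11
  for (rate in c(5, 37.5, 99.9)) {
    a_sample <- a_ctrl + (1 - rate / 100) * a_std
    expect_equal(dpph_scavenging_rate(a_sample, a_ctrl, a_std), rate)
  }
})

test_that("T-AOC inverts the calibration linearly", {
  cal <- fit_standard_curve(c(0, 1), c(0, 1))        # slope 1, intercept 0
  expect_equal(t_aoc(0.42, 0.42, cal, 34), 0)
  expect_equal(t_aoc(0.7, 0.2, cal, 2), 1)
  expect_equal(t_aoc(0.9, 0.2, cal, 2),
               -suppressWarnings(t_aoc(-0.5, 0.2, cal, 2)))
  expect_warning(t_aoc(0.1, 0.3, cal, 2), "negative")
  cal0 <- structure(list(slope = 0, intercept = 0.5, r_squared = 1,
                         n_points = 2L), class = "standard_curve")
  expect_error(t_aoc(1, 0, cal0), "slope")
  expect_error(t_aoc(1, 0, cal, dilution_factor = 0), "positive")
})

test_that("replicate summaries use the sample SD and tolerate n = 1", {
  expect_equal(summarize_replicates(c(1, 1, 1)), list(mean = 1, sd = 0))
  expect_equal(summarize_replicates(c(1, 2, 3)), list(mean = 2, sd = 1))
  one <- summarize_replicates(4.2)
  expect_equal(one$mean, 4.2)
  expect_true(is.na(one$sd))
})

test_that("plate readings reduce to per-batch activities", {
  plate <- data.frame(
    well = sprintf("A%d", 1:6),
    role = c("sample", "sample", "control", "standard", "sample", "control"),
    absorbance = c(0.50, 0.52, 0.10, 0.80, 0.34, 0.10),
    batch_id = c("S1", "S1", "S1", NA, "S2", "S2"))
  out <- plate_activity(plate, mode = "dpph")
  expect_equal(out$value[out$batch_id == "S1"],
               mean(dpph_scavenging_rate(c(0.50, 0.52), 0.10, 0.80)))
  expect_equal(out$value[out$batch_id == "S2"],
               dpph_scavenging_rate(0.34, 0.10, 0.80))
  taoc_plate <- data.frame(
    well = sprintf("B%d", 1:5),
    role = c("calibrant:0", "calibrant:1", "blank", "sample", "sample"),
    absorbance = c(0.0, 0.5, 0.05, 0.30, 0.32),
    batch_id = c(NA, NA, NA, "S1", "S1"))
  out2 <- plate_activity(taoc_plate, mode = "taoc", dilution_factor = 34)
  expect_equal(out2$value, mean(((c(0.30, 0.32) - 0.05) - 0) / 0.5 * 34))
})
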