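test_that("SAC arithmetic follows the blank-corrected dilution formula", {
  expect_equal(compute_sac(od_s = 0.5, od_b = 0.1, w_d = 10, f = 50), 2.0)
  expect_equal(compute_sac(od_s = 0.3, od_b = 0.3, w_d = 7), 0.0)
  expect_equal(compute_sac(od_s = 0.3122, od_b = 0.05, w_d = 10, f = 50),
               1.311)
  # linear in the OD difference, inversely proportional to weight
  expect_equal(compute_sac(0.9, 0.1, 10), 2 * compute_sac(0.5, 0.1, 10))
  expect_equal(compute_sac(0.5, 0.1, 20), compute_sac(0.5, 0.1, 10) / 2)
  expect_error(compute_sac(0.5, 0.1, w_d = 0), "w_d")
  expect_warning(compute_sac(0.1, 0.5, w_d = 10), "negative SAC")
})

test_that("replicate SACs pool to their arithmetic mean with count checks", {
  expect_equal(average_replicates(c(1.9, 2.1))$sample_sac, 2.0)
  expect_equal(average_replicates(c(1, 2, 3, 4))$sample_sac, 2.5)
  expect_warning(one <- average_replicates(2.0), "outside the expected")
  expect_equal(one$sample_sac, 2.0)
  expect_error(average_replicates(numeric(0)), "no replicate")
})

test_that("calibration line endpoints and round-trip inversion are exact", {
  curve <- default_curve()
  expect_equal(as.numeric(sac_to_lignin(0.05, curve)), 0)
  expect_equal(as.numeric(sac_to_lignin(13.11, curve)), 100)
  expect_equal(as.numeric(sac_to_lignin(2.662, curve)), 20, tolerance = 1e-9)
  for (l in c(0, 0.5, 7.7, 20.52, 42.8, 99, 100)) {
    expect_equal(as.numeric(sac_to_lignin(
      rootlignin:::lignin_to_sac(l, curve), curve)), l, tolerance = 1e-9)
  }
  # out-of-range flagged, not clipped
  hi <- sac_to_lignin(14, curve)
  expect_gt(as.numeric(hi), 100)
  expect_true(any(attr(hi, "out_of_range")))
})

test_that("calibration fitting recovers exact and noisy generating lines", {
  amount <- seq(0.05, 0.95, length.out = 10)
  sac_exact <- 0.05 + 13.06 * amount
  cv <- fit_calibration_curve(amount, sac_exact)
  expect_equal(cv$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cv$slope_denominator, 13.06, tolerance = 1e-12)

  # standards built by inverting the curve through simulated readings
  sacs <- vapply(seq(5, 95, by = 10), function(l) {
    r <- simulate_absorbance_readings(l, noise_sd = 0, n_reps = 2, seed = 1)
    mean(compute_sac(r$OD_S, r$OD_B, r$W_d_mg, r$F))
  }, 0)
  cv2 <- fit_calibration_curve(seq(5, 95, by = 10) / 100, sacs)
  expect_equal(cv2$intercept, 0.05, tolerance = 1e-9)
  expect_equal(cv2$slope_denominator, 13.06, tolerance = 1e-9)

  # noisy standards: slope within 3 SE of truth (OLS sampling distribution)
  set.seed(7)
  sac_noisy <- 0.05 + 13.06 * rep(amount, 2) + rnorm(20, 0, 0.2)
  cv3 <- fit_calibration_curve(rep(amount, 2), sac_noisy)
  se_slope <- summary(attr(cv3, "fit"))$coefficients["amount", "Std. Error"]
  expect_lt(abs(cv3$slope_denominator - 13.06), 3 * se_slope)
  expect_error(fit_calibration_curve(rep(0.5, 5), rnorm(5)), "span")
})

test_that("simulated readings invert the quantification arithmetic", {
  r0 <- simulate_absorbance_readings(0, noise_sd = 0, n_reps = 3)
  expect_equal(compute_sac(r0$OD_S, r0$OD_B, r0$W_d_mg, r0$F), rep(0.05, 3))
  r100 <- simulate_absorbance_readings(100, noise_sd = 0, n_reps = 2)
  expect_equal(compute_sac(r100$OD_S, r100$OD_B, r100$W_d_mg, r100$F)[1], 13.11)
  r20 <- simulate_absorbance_readings(20, noise_sd = 0, n_reps = 2)
  sac <- mean(compute_sac(r20$OD_S, r20$OD_B, r20$W_d_mg, r20$F))
  expect_equal(as.numeric(sac_to_lignin(sac)), 20, tolerance = 1e-9)
  expect_error(simulate_absorbance_readings(20, noise_sd = -1), "noise_sd")
})

test_that("replicate spread pools within-sample variability correctly", {
  tbl0 <- data.frame(sample_id = rep(c("a", "b"), each = 3),
                     lignin_pct = rep(c(10, 20), each = 3))
  expect_equal(replicate_spread(tbl0), 0)
  tbl1 <- data.frame(sample_id = "a", lignin_pct = c(18, 22))
  expect_equal(replicate_spread(tbl1), sqrt(8), tolerance = 1e-12)
  expect_error(replicate_spread(data.frame(sample_id = letters[1:3],
                                           lignin_pct = 1:3)), ">= 2")
  # Monte-Carlo consistency: known replicate noise recovered within 10 %
  set.seed(11)
  n_s <- 150
  tbl <- data.frame(sample_id = rep(seq_len(n_s), each = 3),
                    lignin_pct = rep(runif(n_s, 10, 40), each = 3) +
                      rnorm(3 * n_s, 0, 3.6))
  expect_lt(abs(replicate_spread(tbl) - 3.6) / 3.6, 0.1)
})

test_that("a replicates CSV flows through to a lignin reference table", {
  tmp <- tempfile(fileext = ".csv")
  reads <- do.call(rbind, lapply(c(a = 12, b = 30), function(l) {
    simulate_absorbance_readings(l, noise_sd = 0, n_reps = 3, seed = 5)
  }))
  reads$sample_id <- rep(c("a", "b"), each = 3)
  reads$F <- reads$F
  write.csv(reads[, c("sample_id", "replicate_id", "OD_S", "OD_B",
                      "W_d_mg", "F")], tmp, row.names = FALSE)
  ref <- wetchem_reference(tmp)
  expect_equal(ref$sample_id, c("a", "b"))
  expect_equal(ref$lignin_pct, c(12, 30), tolerance = 1e-9)
  expect_equal(ref$n_replicates, c(3L, 3L))
  unlink(tmp)
})
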