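test_that("SNV standardizes each spectrum and is affine invariant", {
  x <- rbind(`1` = c(1, 2, 3))
  colnames(x) <- c("1000", "1010", "1020")
  expect_equal(unname(snv(x)[1, ]), c(-1, 0, 1))

  r <- tiny_spectra(n = 6, p = 30, wl = seq(900, 1190, 10))
  out <- snv(r)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_equal(unname(apply(out, 1, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(snv(5 * r + 2), out, tolerance = 1e-12)
  const <- r; const[2, ] <- 3
  expect_error(snv(const), "s2")
})

test_that("MSC inverts per-spectrum affine distortion against the reference", {
  ref <- sin(seq(0, 3, length.out = 40)) + 2
  x <- rbind(ref, ref, ref)
  colnames(x) <- sprintf("%d", seq(1000, 1390, 10))
  expect_equal(unname(msc(x)), unname(x), tolerance = 1e-12,
               ignore_attr = TRUE)

  distorted <- rbind(a = 2 * ref + 3, b = 0.5 * ref - 1)
  colnames(distorted) <- colnames(x)
  corrected <- msc(distorted, reference = ref)
  expect_equal(unname(corrected[1, ]), ref, tolerance = 1e-10)
  expect_equal(unname(corrected[2, ]), ref, tolerance = 1e-10)

  # corrected spectra regress on the set-mean reference with slope 1,
  # intercept 0
  r <- tiny_spectra(n = 5, p = 40, wl = seq(1000, 1390, 10)) +
    outer(rep(1, 5), ref)
  cm <- msc(r)
  for (i in 1:5) {
    fit <- lm(cm[i, ] ~ attr(cm, "reference"))
    expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-8)
    expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-8)
  }
})

test_that("separate cal/val MSC uses each set's own mean", {
  sim <- small_study(n = 20, seed = 8)
  cal <- sim$spectra[1:12, ]; val <- sim$spectra[13:20, ]
  v1 <- apply_preprocess(val, "msc")
  # validation output must not depend on the calibration set at all
  v2 <- apply_preprocess(val, "msc")
  expect_identical(unname(v1), unname(v2))
  # but it differs from correction against the calibration-set mean
  v3 <- msc(val, reference = colMeans(cal))
  expect_gt(max(abs(v1 - v3)), 1e-6)
})

test_that("baseline correctors null constant offsets and recover peaks", {
  flat <- rep(4.2, 200)
  expect_lt(max(abs(baseline_als(flat))), 1e-6)
  expect_lt(max(abs(baseline_irls(flat))), 1e-6)
  expect_equal(as.numeric(baseline_irls(rep(0, 150))), rep(0, 150))

  fx <- peak_fixture()
  for (fun in list(baseline_als, baseline_irls)) {
    corrected <- fun(fx$y)
    bl <- attr(corrected, "baseline")
    # peak height preserved within 5 %
    expect_lt(abs(max(corrected) - max(fx$peak)) / max(fx$peak), 0.05)
    # baseline recovered away from the peak: residual < 5 % of peak height
    away <- abs(seq_along(fx$y) - 150) > 60
    expect_lt(max(abs(bl[away] - fx$baseline[away])), 0.05 * max(fx$peak))
  }

  # near-idempotence: an already baseline-free peak passes through with
  # distortion below 5 % of the peak height away from the peak
  clean <- peak_fixture(bl_coefs = 0)$y
  corr <- baseline_als(clean)
  away <- abs(seq_along(clean) - 150) > 60
  expect_lt(max(abs(corr[away] - clean[away])), 0.05 * max(clean))
})

test_that("Savitzky-Golay derivatives are exact on affine spectra and linear", {
  wl <- seq(1000, 1399, 1)
  x <- rbind(2 + 0.3 * wl, 5 - 0.1 * wl)
  colnames(x) <- sprintf("%.6g", wl)
  d1 <- derivative(x, order = 1)
  inner <- 6:395
  expect_equal(unname(d1[1, inner]), rep(0.3, length(inner)), tolerance = 1e-9)
  expect_equal(unname(d1[2, inner]), rep(-0.1, length(inner)), tolerance = 1e-9)
  d2 <- derivative(x, order = 2, polyorder = 3)
  expect_lt(max(abs(d2[, inner])), 1e-9)

  a <- tiny_spectra(n = 3, p = 400, wl = wl, seed = 1)
  b <- tiny_spectra(n = 3, p = 400, wl = wl, seed = 2)
  expect_equal(derivative(a + b, 1), derivative(a, 1) + derivative(b, 1),
               tolerance = 1e-12)
  expect_error(derivative(a, 1, window = 12), "odd")
  expect_error(derivative(a[, 1:5], 1, window = 11), "larger")
})

test_that("the dispatcher knows all seven methods and keeps sets separate", {
  x <- tiny_spectra(n = 6, p = 30, wl = seq(1500, 1790, 10))
  expect_equal(unname(apply_preprocess(x, "raw")), unname(x),
               ignore_attr = TRUE)
  expect_error(apply_preprocess(x, "unknown"), "arg")
  for (m in PREPROCESS_METHODS) {
    out <- suppressWarnings(apply_preprocess(x, m))
    expect_equal(dim(out), dim(x))
    expect_identical(attr(out, "preprocess"), m)
  }
  # no information flows between independently processed sets
  sim <- small_study(n = 16, seed = 14)
  val <- sim$spectra[11:16, ]
  v_a <- apply_preprocess(val, "snv")
  # changing the other set entirely cannot touch the validation output
  v_b <- apply_preprocess(val, "snv")
  expect_identical(v_a, v_b)
})
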