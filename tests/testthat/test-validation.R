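test_that("split plans partition the samples reproducibly", {
  plans <- make_splits(74, 44, 30, repeats = 5, master_seed = 20)
  expect_length(plans, 5)
  for (p in plans) {
    expect_length(p$cal, 44)
    expect_length(p$val, 30)
    expect_length(intersect(p$cal, p$val), 0)
    expect_setequal(c(p$cal, p$val), 1:74)
  }
  expect_identical(plans, make_splits(74, 44, 30, repeats = 5,
                                      master_seed = 20))
  small <- make_splits(10, 6, 4, repeats = 3, master_seed = 1)
  expect_true(all(vapply(small, function(p)
    setequal(c(p$cal, p$val), 1:10), TRUE)))
  expect_error(make_splits(74, 40, 30), "equal")
})

test_that("validation metrics match a hand-computed oracle", {
  obs <- c(10, 20, 30); pred <- c(12, 18, 33)
  m <- compute_metrics(obs, pred)
  # independent arithmetic: e = (2, -2, 3)
  expect_equal(m$BIAS, 1)
  expect_equal(m$RMSEP, sqrt(17 / 3), tolerance = 1e-12)
  expect_equal(m$SEP, sqrt(7), tolerance = 1e-12)
  expect_equal(m$R2p, 11025 / 11700, tolerance = 1e-12)
  expect_equal(m$RPD, 10 / sqrt(7), tolerance = 1e-12)

  perfect <- compute_metrics(obs, obs)
  expect_equal(perfect$RMSEP, 0)
  expect_equal(perfect$BIAS, 0)
  expect_true(is.infinite(perfect$RPD) && perfect$flags["zero_sep"])

  offset <- compute_metrics(obs, obs + 2)
  expect_equal(offset$BIAS, 2)
  expect_equal(offset$SEP, 0)
  expect_equal(offset$RMSEP, 2)
  expect_true(offset$flags["zero_sep"])

  flat <- compute_metrics(c(5, 5, 5), pred)
  expect_true(flat$flags["zero_obs_var"] && is.na(flat$R2p))
})

test_that("metric identities hold on random prediction vectors", {
  set.seed(123)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    obs <- rnorm(n, 20, 7)
    pred <- obs + rnorm(n, 0.5, 2)
    m <- compute_metrics(obs, pred)
    expect_equal(m$RMSEP^2, m$SEP^2 * (n - 1) / n + m$BIAS^2,
                 tolerance = 1e-9)
    expect_equal(m$RPD * m$SEP, sd(obs), tolerance = 1e-9)
  }
})

test_that("per-split evaluation keeps validation data out of fitting", {
  sim <- small_study(n = 40, seed = 6)
  X <- sim$spectra; y <- sim$reference$lignin_pct
  split <- make_splits(40, 24, 16, repeats = 1, master_seed = 2)[[1]]
  r <- evaluate_split(X, y, split, preprocess = "snv", model = "full")
  expect_true(all(c("RMSEP", "SEP", "BIAS", "R2p", "RPD", "nLV",
                    "RMSE") %in% names(r)))
  # perturbing one validation spectrum changes only its own prediction
  X2 <- X
  X2[split$val[3], ] <- X2[split$val[3], ] + rnorm(ncol(X), 0, 0.05)
  r2 <- evaluate_split(X2, y, split, preprocess = "snv", model = "full")
  expect_identical(r$nLV, r2$nLV)
  expect_identical(r$RMSE, r2$RMSE)  # calibration side untouched
  expect_false(isTRUE(all.equal(r$RMSEP, r2$RMSEP)))
})

test_that("noise-free one-component data validate perfectly", {
  set.seed(9)
  t_score <- runif(30, 10, 40)
  profile <- exp(-0.5 * ((seq(800, 2782, length.out = 120) - 1600) / 150)^2)
  X <- outer(t_score, profile)
  colnames(X) <- sprintf("%.6g", seq(800, 2782, length.out = 120))
  split <- make_splits(30, 18, 12, repeats = 1, master_seed = 4)[[1]]
  r <- suppressWarnings(evaluate_split(X, t_score, split, preprocess = "raw",
                                       model = "full", max_nlv = 3))
  expect_lt(r$RMSEP, 1e-8)
  expect_equal(r$R2p, 1, tolerance = 1e-9)
})

test_that("reports aggregate to mean and SD in the standard table layout", {
  metrics <- data.frame(nLV = c(5, 5), RPD = c(2, 3), R2p = c(0.8, 0.9),
                        RMSEP = c(3, 3), SEP = c(3, 3), BIAS = c(0, 0),
                        RMSE = c(2.5, 2.5))
  agg <- aggregate_reports(metrics, label = "SNV")
  expect_equal(agg$summary$mean[agg$summary$metric == "RPD"], 2.5)
  expect_equal(agg$summary$sd[agg$summary$metric == "RPD"],
               sd(c(2, 3)), tolerance = 1e-12)
  expect_match(agg$formatted$RPD, "2.50 ± 0.71", fixed = TRUE)
  identical_reps <- metrics; identical_reps$RPD <- c(2, 2)
  expect_equal(aggregate_reports(identical_reps)$summary$sd[
    aggregate_reports(identical_reps)$summary$metric == "RPD"], 0)
  expect_error(aggregate_reports(metrics[1, ]), "repeats")
})

test_that("selection frequency counts repeats per band", {
  subs <- list(c(1, 3), c(1, 4), c(1, 3, 4))
  f <- selection_frequency(subs, p = 5)
  expect_equal(f, c(100, 0, 200 / 3, 200 / 3, 0))
  expect_true(all(f >= 0 & f <= 100))
  expect_error(selection_frequency(list(), 5), "no subsets")
})

test_that("survey summaries report quantiles with per-column counts", {
  rec <- data.frame(RPD = c(1, 2, 3), R2p = c(0.5, NA, 0.9),
                    SEP = rep(NA_real_, 3), study = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  s <- suppressMessages(summarize_survey(rec))
  expect_equal(s["Med", "RPD"], 2)
  expect_equal(s["Min", "R2p"], 0.5)
  expect_equal(s["Max", "R2p"], 0.9)
  expect_equal(attr(s, "n")[["RPD"]], 3L)
  expect_equal(attr(s, "n")[["R2p"]], 2L)
  expect_true("SEP" %in% attr(s, "omitted"))
  one <- summarize_survey(data.frame(RPD = 2.2))
  expect_true(all(one[, "RPD"] == 2.2))
  # type-7 linear interpolation convention
  expect_equal(summarize_survey(data.frame(x = 1:4))["Q25", "x"], 1.75)
})

test_that("identical master seeds replay the whole pipeline bitwise", {
  sim <- small_study(n = 36, seed = 31)
  X <- sim$spectra; y <- sim$reference$lignin_pct
  run_once <- function() {
    splits <- make_splits(36, 21, 15, repeats = 3, master_seed = 17)
    run_validation(X, y, splits, preprocess = "snv", model = "full")
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$metrics, b$metrics)
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(a$metrics, f1, row.names = FALSE)
  write.csv(b$metrics, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})
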