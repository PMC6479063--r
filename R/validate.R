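#' Seeded calibration/validation split plans
#'
#' Draws `repeats` random partitions of `n` samples into disjoint
#' calibration and validation sets (defaults mirror the 74 = 44 + 30
#' design). Each plan carries its own seed, derived from the master seed,
#' so Block I (full-spectrum) and Block II (CARS) runs can reuse
#' byte-identical splits and so any single repeat can be replayed.
#'
#' @param n total number of samples (default 74).
#' @param n_cal calibration-set size (default 44).
#' @param n_val validation-set size (default 30); `n_cal + n_val` must
#'   equal `n`.
#' @param repeats number of random splits (default 100).
#' @param master_seed integer master seed.
#' @return list of plans, each `list(repeat_index, seed, cal, val)`.
#' @export
make_splits <- function(n = 74L, n_cal = 44L, n_val = 30L, repeats = 100L,
                        master_seed = 1L) {
  if (n_cal + n_val != n) stop("n_cal + n_val must equal n")
  if (n_cal < 2 || n_val < 2) stop("both sets need >= 2 samples")
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  lapply(seq_len(repeats), function(r) {
    set.seed(seeds[r])
    idx <- sample.int(n)
    list(repeat_index = r, seed = seeds[r],
         cal = sort(idx[seq_len(n_cal)]),
         val = sort(idx[n_cal + seq_len(n_val)]))
  })
}

#' Validation metrics for predicted vs observed values
#'
#' Standard chemometric accuracy measures on a hold-out set:
#' BIAS = mean(pred - obs); RMSEP = sqrt(mean((pred - obs)^2));
#' SEP = sqrt(sum((e - BIAS)^2) / (n - 1)) (bias-corrected, n-1
#' denominator, which makes RMSEP^2 = SEP^2 (n-1)/n + BIAS^2 exact);
#' R2p = squared Pearson correlation of predicted and observed (the
#' `"scatter"` variant 1 - SSE/SST is available); RPD = sd(obs) / SEP.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @param r2_variant `"pearson"` (default) or `"scatter"` (1 - SSE/SST).
#' @return list with `RMSEP`, `SEP`, `BIAS`, `R2p`, `RPD`, `n`, and
#'   logical `flags` (`zero_sep`, `zero_obs_var`) for degenerate cases
#'   where RPD or R2p is infinite/undefined.
#' @export
compute_metrics <- function(observed, predicted,
                            r2_variant = c("pearson", "scatter")) {
  r2_variant <- match.arg(r2_variant)
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  e <- predicted - observed
  n <- length(e)
  bias <- mean(e)
  rmsep <- sqrt(mean(e^2))
  sep <- sqrt(sum((e - bias)^2) / (n - 1))
  sd_obs <- stats::sd(observed)
  flags <- c(zero_sep = sep == 0, zero_obs_var = sd_obs == 0)
  r2 <- if (flags["zero_obs_var"] || sep == 0 && r2_variant == "pearson") {
    if (flags["zero_obs_var"]) NA_real_ else 1
  } else if (r2_variant == "pearson") {
    stats::cor(observed, predicted)^2
  } else {
    1 - sum(e^2) / sum((observed - mean(observed))^2)
  }
  rpd <- if (sep == 0) Inf else sd_obs / sep
  list(RMSEP = rmsep, SEP = sep, BIAS = bias, R2p = r2, RPD = rpd,
       n = n, flags = flags)
}

#' Evaluate one calibration/validation split
#'
#' Runs the per-split pipeline with strict separation of the two sets:
#' pre-process the calibration and validation spectra independently (the
#' operational convention — a deployed model meets new spectra whose
#' pre-processing cannot peek at the calibration set), optionally run
#' CARS wavelength selection on the calibration set, choose nLV by
#' ten-fold CV on the calibration set, fit, and predict the validation
#' set. No validation information enters selection or fitting.
#'
#' @param X full spectra matrix.
#' @param y full reference lignin vector (aligned with `X` rows).
#' @param split one plan from [make_splits()].
#' @param preprocess method name for [apply_preprocess()].
#' @param model `"full"` (full-spectrum PLSR) or `"cars"` (CARS-PLSR).
#' @param max_nlv nLV search cap (default 15).
#' @param folds CV folds (default 10).
#' @param cars_runs,mc_ratio CARS settings (see [cars_config()]).
#' @param ... extra pre-processing parameters.
#' @return list of class `metrics_report`: the [compute_metrics()] fields
#'   plus `nLV`, `RMSE` (calibration), `n_bands`, `subset` (selected band
#'   indices; all bands for `"full"`), `repeat_index`.
#' @export
evaluate_split <- function(X, y, split, preprocess = "snv",
                           model = c("full", "cars"), max_nlv = 15L,
                           folds = 10L, cars_runs = 50L, mc_ratio = 0.8, ...) {
  model <- match.arg(model)
  set.seed(split$seed + 1L)
  X_cal <- tryCatch(apply_preprocess(X[split$cal, , drop = FALSE],
                                     preprocess, ...),
                    error = function(e) stop("calibration-set preprocessing (",
                                             preprocess, ") failed: ",
                                             conditionMessage(e)))
  X_val <- tryCatch(apply_preprocess(X[split$val, , drop = FALSE],
                                     preprocess, ...),
                    error = function(e) stop("validation-set preprocessing (",
                                             preprocess, ") failed: ",
                                             conditionMessage(e)))
  y_cal <- y[split$cal]; y_val <- y[split$val]
  subset <- seq_len(ncol(X_cal))
  if (model == "cars") {
    trace <- run_cars(X_cal, y_cal,
                      cars_config(n_runs = cars_runs, mc_ratio = mc_ratio,
                                  folds = folds, max_nlv = max_nlv,
                                  seed = split$seed + 2L))
    subset <- trace$best_subset
  }
  cv <- cross_validate_nlv(X_cal[, subset, drop = FALSE], y_cal,
                           max_nlv = max_nlv, folds = folds,
                           seed = split$seed + 3L)
  fit <- suppressWarnings(fit_pls(X_cal[, subset, drop = FALSE], y_cal,
                                  cv$chosen_nlv, band_indices = subset))
  pred_val <- predict(fit, X_val[, subset, drop = FALSE])
  m <- compute_metrics(y_val, pred_val)
  m$nLV <- fit$nlv
  m$RMSE <- sqrt(mean((fit$fitted - y_cal)^2))
  m$n_bands <- length(subset)
  m$subset <- subset
  m$repeat_index <- split$repeat_index
  class(m) <- "metrics_report"
  m
}

#' Run the repeated outer validation
#'
#' Applies [evaluate_split()] to every plan and binds the per-repeat
#' metrics into a data frame; the per-repeat selected subsets are kept
#' for [selection_frequency()].
#'
#' @inheritParams evaluate_split
#' @param splits list of plans from [make_splits()].
#' @return list with `metrics` (data frame: repeat_index, nLV, RMSE,
#'   RPD, R2p, RMSEP, SEP, BIAS, n_bands) and `subsets` (list of band
#'   index vectors).
#' @export
run_validation <- function(X, y, splits, preprocess = "snv", model = "full",
                           max_nlv = 15L, folds = 10L, cars_runs = 50L,
                           mc_ratio = 0.8, ...) {
  reports <- lapply(splits, function(s) {
    evaluate_split(X, y, s, preprocess = preprocess, model = model,
                   max_nlv = max_nlv, folds = folds, cars_runs = cars_runs,
                   mc_ratio = mc_ratio, ...)
  })
  metrics <- do.call(rbind, lapply(reports, function(r) {
    data.frame(repeat_index = r$repeat_index, nLV = r$nLV, RMSE = r$RMSE,
               RPD = r$RPD, R2p = r$R2p, RMSEP = r$RMSEP, SEP = r$SEP,
               BIAS = r$BIAS, n_bands = r$n_bands)
  }))
  list(metrics = metrics, subsets = lapply(reports, `[[`, "subset"))
}

#' Aggregate per-repeat metrics into a mean +/- SD row
#'
#' @param metrics per-repeat metrics data frame from [run_validation()].
#' @param label row label (e.g. the pre-processing method or model name).
#' @return list with `summary` (data frame of mean and SD per metric,
#'   plus the repeat count) and `formatted` (one-row data frame of
#'   "mean +/- SD" strings in the conventional table layout).
#' @export
aggregate_reports <- function(metrics, label = "model") {
  if (nrow(metrics) < 2) stop("need >= 2 repeats to aggregate")
  cols <- c("nLV", "RPD", "R2p", "RMSEP", "SEP", "BIAS", "RMSE")
  cols <- intersect(cols, names(metrics))
  mu <- vapply(metrics[cols], mean, 0)
  sdv <- vapply(metrics[cols], stats::sd, 0)
  fmt <- vapply(cols, function(cn) {
    sprintf("%.2f ± %.2f", mu[cn], sdv[cn])
  }, "")
  list(summary = data.frame(label = label, metric = cols, mean = unname(mu),
                            sd = unname(sdv), repeats = nrow(metrics)),
       formatted = stats::setNames(data.frame(label, t(fmt)),
                                   c("Method", cols)))
}

#' Per-band wavelength selection frequency
#'
#' Fraction (in %) of outer repeats in which each band appeared in the
#' CARS best subset — the selection-importance profile over the grid.
#'
#' @param subsets list of selected band-index vectors, one per repeat.
#' @param p number of bands in the grid.
#' @return numeric vector of length `p` with values in [0, 100].
#' @export
selection_frequency <- function(subsets, p) {
  if (length(subsets) == 0) stop("no subsets supplied")
  counts <- tabulate(unlist(subsets), nbins = p)
  100 * counts / length(subsets)
}

#' Quantile summary of a literature-survey table
#'
#' Column-wise minimum, quartiles, median and maximum (type-7 linear
#' interpolation) of study-level survey records, ignoring missing
#' entries; each column's non-missing count is reported alongside.
#' Columns with no data are omitted with a note.
#'
#' @param records data frame of numeric columns (e.g. species count,
#'   sample mass, val/cal ratio, RPD, R2p, RMSEP, SEP); blanks as `NA`.
#' @return data frame with rows Min, Q25, Med, Q75, Max and an `n`
#'   attribute per column; omitted columns recorded in attribute
#'   `"omitted"`.
#' @export
summarize_survey <- function(records) {
  num <- records[vapply(records, is.numeric, TRUE)]
  if (ncol(num) == 0) stop("no numeric columns to summarize")
  ns <- vapply(num, function(v) sum(!is.na(v)), 0L)
  omitted <- names(ns)[ns == 0]
  if (length(omitted)) {
    message("omitting empty column(s): ", paste(omitted, collapse = ", "))
  }
  keep <- names(ns)[ns > 0]
  qs <- vapply(num[keep], function(v) {
    stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE, type = 7)
  }, numeric(5))
  out <- as.data.frame(qs)
  rownames(out) <- c("Min", "Q25", "Med", "Q75", "Max")
  attr(out, "n") <- ns[keep]
  attr(out, "omitted") <- omitted
  out
}
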