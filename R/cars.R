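#' Exponentially decreasing retention fraction (EDF)
#'
#' The fraction of the p spectral bands retained by forced removal at
#' sampling run i of N follows r_i = a * exp(-k * i) with
#' a = (p/2)^(1/(N-1)) and k = log(p/2) / (N-1), so that r_1 = 1 (all
#' bands survive the first run) and r_N = 2/p (two bands survive the
#' last).
#'
#' @param i run index (1..N), vectorized.
#' @param n_runs total number of sampling runs N (>= 2).
#' @param p number of spectral bands (>= 3).
#' @return retention fraction(s) in (0, 1].
#' @export
edf_ratio <- function(i, n_runs, p) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (p < 3) stop("p must be >= 3")
  stopifnot(all(i >= 1), all(i <= n_runs))
  # algebraically identical to a*exp(-k*i) with a = (p/2)^(1/(N-1)) and
  # k = log(p/2)/(N-1), but endpoint-exact in floating point:
  # the exponent is 0 at i = 1 and -1 at i = N
  (p / 2)^((1 - i) / (n_runs - 1))
}

#' Adaptive reweighted sampling of wavelengths
#'
#' Draws `n_draw` wavelengths with replacement, with probability
#' proportional to the supplied nonnegative weights (in CARS: the
#' normalized absolute PLS regression coefficients), and returns the set
#' of distinct drawn indices. Because draws are with replacement the
#' returned set can be smaller than `n_draw`; low-weight bands may miss
#' every draw and drop out — that is the competitive element.
#'
#' @param weights nonnegative per-band weights (sum > 0).
#' @param n_draw number of draws.
#' @param seed RNG seed; `NULL` uses the current stream.
#' @return sorted integer vector of retained band indices.
#' @export
ars_sample <- function(weights, n_draw, seed = NULL) {
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("all-zero weights: nothing to sample")
  if (!is.null(seed)) set.seed(seed)
  drawn <- sample.int(length(weights), size = n_draw, replace = TRUE,
                      prob = weights / sum(weights))
  sort(unique(drawn))
}

#' CARS configuration
#'
#' @param n_runs number of sampling runs N (default 50).
#' @param mc_ratio fraction of calibration samples drawn (without
#'   replacement) for each run's coefficient fit (default 0.8).
#' @param folds inner cross-validation folds for the per-run RMSECV
#'   (default 10).
#' @param max_nlv latent-variable cap for all inner fits (default 15).
#' @param seed RNG seed for the whole trace.
#' @return list of class `cars_config`.
#' @export
cars_config <- function(n_runs = 50L, mc_ratio = 0.8, folds = 10L,
                        max_nlv = 15L, seed = 1L) {
  if (n_runs < 2) stop("n_runs must be >= 2")
  if (mc_ratio <= 0 || mc_ratio > 1) stop("mc_ratio must be in (0, 1]")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(n_runs = as.integer(n_runs), mc_ratio = mc_ratio,
                 folds = as.integer(folds), max_nlv = as.integer(max_nlv),
                 seed = as.integer(seed)),
            class = "cars_config")
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Wraps the PLS1 engine in N sampling runs. The component count for the
#' per-run coefficient fits is fixed up front by ten-fold CV on the full
#' calibration spectra. Run i: (1) draw
#' `mc_ratio` of the calibration samples (Monte Carlo); (2) fit PLS on
#' the currently retained bands of that subset and take the absolute
#' regression coefficients as band weights; (3) forced removal — keep
#' only the top ceiling(r_i * p) bands by weight, r_i from [edf_ratio()];
#' (4) adaptive reweighted sampling within the survivors
#' ([ars_sample()], with p draws, so the EDF sets the retention
#' schedule while ARS competitively drops low-weight survivors) to
#' obtain the next retained set; (5) record the
#' ten-fold RMSECV (with CV-chosen nLV) of a PLS model on the full
#' calibration set restricted to that retained set. The best subset is
#' the retained set of the run with minimal RMSECV.
#'
#' The forced-removal target is clamped to the current retained-set size
#' (ARS can shrink a set below the next EDF target) and the retained set
#' is clamped below at 2 bands (with a warning).
#'
#' @param X calibration spectra matrix (n x p, p >= 3).
#' @param y calibration responses.
#' @param cfg a [cars_config()].
#' @return object of class `cars_trace`: data frame `runs` (run,
#'   n_retained, retention_ratio, rmsecv, nlv), list `retained_sets`,
#'   `best_run`, `best_subset`, `cfg`.
#' @export
run_cars <- function(X, y, cfg = cars_config()) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, p >= 3)
  set.seed(cfg$seed)
  retained <- seq_len(p)
  n_mc <- max(2L, round(cfg$mc_ratio * n))
  # Component count for the per-run coefficient fits, fixed up front by
  # ten-fold CV on the full calibration spectra: weight vectors must come
  # from a sensibly regularized model, not from the largest fit the data
  # admit, or ARS samples noise-aligned bands.
  nlv0 <- cross_validate_nlv(X, y, max_nlv = cfg$max_nlv,
                             folds = cfg$folds)$chosen_nlv
  runs <- data.frame(run = seq_len(cfg$n_runs), n_retained = NA_integer_,
                     retention_ratio = NA_real_, rmsecv = NA_real_,
                     nlv = NA_integer_)
  sets <- vector("list", cfg$n_runs)
  for (i in seq_len(cfg$n_runs)) {
    mc <- sample.int(n, n_mc)
    nlv_fit <- min(nlv0, n_mc - 1L, length(retained))
    fit <- suppressWarnings(fit_pls(X[mc, retained, drop = FALSE], y[mc],
                                    nlv_fit))
    w <- abs(fit$coefficients)
    w <- w / sum(w)
    r_i <- edf_ratio(i, cfg$n_runs, p)
    n_keep <- max(2L, min(ceiling(r_i * p), length(retained)))
    top <- order(w, decreasing = TRUE)[seq_len(n_keep)]
    survivors <- retained[top]
    sw <- w[top]
    new_set <- if (sum(sw) > 0) {
      survivors[ars_sample(sw, n_draw = p)]
    } else {
      survivors
    }
    if (length(new_set) < 2L) {
      warning("run ", i, ": retained set below 2 bands; clamping to top 2")
      new_set <- survivors[seq_len(2L)]
    }
    retained <- sort(new_set)
    cv <- cross_validate_nlv(X[, retained, drop = FALSE], y,
                             max_nlv = cfg$max_nlv, folds = cfg$folds)
    runs$n_retained[i] <- length(retained)
    runs$retention_ratio[i] <- r_i
    runs$rmsecv[i] <- min(cv$rmsecv)
    runs$nlv[i] <- cv$chosen_nlv
    sets[[i]] <- retained
  }
  trace <- structure(list(runs = runs, retained_sets = sets, cfg = cfg),
                     class = "cars_trace")
  trace$best_run <- select_best_run(trace)
  trace$best_subset <- sets[[trace$best_run]]
  trace
}

select_best_run <- function(trace) {
  r <- trace$runs
  ord <- order(r$rmsecv, r$n_retained, r$run)
  ord[1]
}

#' Best wavelength subset of a CARS trace
#'
#' The retained set of the run with the smallest inner-CV RMSECV; ties go
#' to the smaller subset, then to the earlier run.
#'
#' @param trace a `cars_trace` from [run_cars()].
#' @return sorted integer vector of band indices.
#' @export
select_best <- function(trace) {
  if (!inherits(trace, "cars_trace") || nrow(trace$runs) == 0) {
    stop("empty or invalid CARS trace")
  }
  trace$retained_sets[[select_best_run(trace)]]
}

#' @export
print.cars_trace <- function(x, ...) {
  cat("CARS trace: ", nrow(x$runs), " runs; best run ", x$best_run,
      " retains ", length(x$best_subset), " band(s), RMSECV ",
      signif(x$runs$rmsecv[x$best_run], 4), "\n", sep = "")
  invisible(x)
}

#' Cluster adjacent selected wavelengths
#'
#' Reporting helper: groups a selected band-index set into clusters of
#' adjacent (or near-adjacent) grid positions, mirroring how a handful of
#' selected wavelengths is read as a few chemically interpretable
#' regions.
#'
#' @param subset sorted band indices.
#' @param gap maximum index gap within a cluster (default 1 = strictly
#'   adjacent).
#' @return integer cluster id per selected band.
#' @export
cluster_adjacent <- function(subset, gap = 1L) {
  if (length(subset) == 0) return(integer(0))
  c(0L, cumsum(diff(subset) > gap)) + 1L
}
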