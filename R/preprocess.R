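#' Standard normal variate transform
#'
#' Standardizes each spectrum to mean 0 and sample SD 1 (n-1 denominator),
#' removing per-spectrum multiplicative scatter and additive offset. Acts
#' on each spectrum alone, so calibration and validation sets can be
#' treated independently without information flow.
#'
#' @param x spectra matrix.
#' @return transformed spectra matrix of the same shape.
#' @export
snv <- function(x) {
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  if (any(sdv == 0)) {
    stop("constant spectrum (zero SD) for sample(s): ",
         paste(rownames(x)[sdv == 0] %||% which(sdv == 0), collapse = ", "))
  }
  (x - mu) / sdv
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed on a reference spectrum (OLS,
#' x ~ a + b * ref) and corrected as (x - a) / b. The reference defaults
#' to the mean spectrum of the set being processed — the convention that
#' makes MSC results diverge when calibration and validation sets are
#' corrected separately, since their mean spectra differ. Pass a fixed
#' `reference` for operational use on new samples.
#'
#' @param x spectra matrix.
#' @param reference optional reference spectrum (length = bands); default
#'   is `colMeans(x)`.
#' @return corrected spectra matrix; the reference used is attached as
#'   attribute `"reference"`.
#' @export
msc <- function(x, reference = NULL) {
  if (is.null(reference)) {
    if (nrow(x) < 2) stop("MSC needs >= 2 spectra when no reference is given")
    reference <- colMeans(x)
  }
  stopifnot(length(reference) == ncol(x))
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- x
  for (i in seq_len(nrow(x))) {
    b <- sum((x[i, ] - mean(x[i, ])) * rc) / denom
    if (abs(b) < 1e-10) {
      stop("MSC slope ~ 0 for sample ", rownames(x)[i] %||% i)
    }
    a <- mean(x[i, ]) - b * mean(reference)
    out[i, ] <- (x[i, ] - a) / b
  }
  attr(out, "reference") <- reference
  out
}

# Whittaker second-difference smoother core shared by both baseline
# estimators: solves (W + lambda D'D) z = W y with sparse banded algebra.
whittaker_solve <- function(y, w, lambda) {
  p <- length(y)
  D <- Matrix::bandSparse(p - 2, p, k = 0:2,
                          diagonals = list(rep(1, p - 2), rep(-2, p - 2),
                                           rep(1, p - 2)))
  W <- Matrix::Diagonal(p, w)
  as.numeric(Matrix::solve(W + lambda * Matrix::crossprod(D), w * y))
}

#' Asymmetric least squares baseline correction
#'
#' Estimates a smooth baseline by second-difference-penalized weighted
#' least squares with asymmetric weights: points above the current
#' baseline (peaks) get weight `p`, points below get `1 - p`. Iterated
#' until the weight assignment stabilizes or `max_iter` is reached; the
#' baseline is subtracted from the spectrum.
#'
#' @param y a single spectrum (numeric vector) or spectra matrix (rows
#'   processed independently).
#' @param lambda smoothness penalty (> 0; default 1e6 — strongly smooth
#'   on a ~662-point grid).
#' @param p asymmetry weight in (0, 1) for points above the baseline
#'   (default 0.05).
#' @param max_iter maximum reweighting iterations (default 10).
#' @return baseline-corrected spectrum/matrix; the estimated baseline is
#'   attached as attribute `"baseline"`.
#' @export
baseline_als <- function(y, lambda = 1e6, p = 0.05, max_iter = 10L) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (p <= 0 || p >= 1) stop("asymmetry p must be in (0, 1)")
  if (is.matrix(y)) return(apply_rows_baseline(y, baseline_als,
                                               lambda = lambda, p = p,
                                               max_iter = max_iter))
  w <- rep(1, length(y))
  z <- y
  eps <- 1e-7 * max(abs(y), 1)  # guards against weight flip-flop on ties
  for (it in seq_len(max_iter)) {
    z <- whittaker_solve(y, w, lambda)
    w_new <- ifelse(y > z + eps, p, 1 - p)
    if (all(w_new == w) && it > 1) break
    if (it == max_iter && !all(w_new == w)) {
      warning("baseline_als: weights not converged after ", max_iter,
              " iterations; returning current estimate")
    }
    w <- w_new
  }
  structure(y - z, baseline = z)
}

#' Iteratively restricted least squares baseline correction
#'
#' Penalized smoothing in which points lying far above the current
#' baseline are progressively down-weighted ("restricted") with a smooth
#' logistic weight of the positive residual, scaled by the residual SD.
#' Points at or below the baseline keep full weight.
#'
#' @param y spectrum vector or spectra matrix.
#' @param lambda smoothness penalty (default 1e6).
#' @param max_iter maximum reweighting iterations (default 10).
#' @param tol relative change in baseline for convergence (default 1e-6).
#' @return corrected spectrum/matrix with attribute `"baseline"`.
#' @export
baseline_irls <- function(y, lambda = 1e6, max_iter = 10L, tol = 1e-6) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (is.matrix(y)) return(apply_rows_baseline(y, baseline_irls,
                                               lambda = lambda,
                                               max_iter = max_iter, tol = tol))
  w <- rep(1, length(y))
  z <- rep(mean(y), length(y))
  for (it in seq_len(max_iter)) {
    z_new <- whittaker_solve(y, w, lambda)
    r <- y - z_new
    s <- stats::sd(r)
    if (s == 0) { z <- z_new; break }
    w <- 1 / (1 + exp(6 * (r / s - 0.5)))  # restrict strong positive residuals
    delta <- sqrt(mean((z_new - z)^2)) / (sqrt(mean(z_new^2)) + 1e-12)
    z <- z_new
    if (delta < tol) break
    if (it == max_iter) {
      warning("baseline_irls: not converged after ", max_iter,
              " iterations; returning current estimate")
    }
  }
  structure(y - z, baseline = z)
}

apply_rows_baseline <- function(x, fun, ...) {
  out <- t(apply(x, 1, function(r) as.numeric(fun(r, ...))))
  dimnames(out) <- dimnames(x)
  out
}

#' Savitzky-Golay spectral derivatives
#'
#' First or second derivative along the band axis by Savitzky-Golay
#' local-polynomial filtering (`signal::sgolayfilt`), which fits edge
#' points with one-sided polynomials so the output keeps the full band
#' count. Derivatives are computed along the band index and scaled by the
#' local grid spacing (first order: 1/h, second order: 1/h^2 with h the
#' band-wise gradient of wavelength over index), so they are returned per
#' nm; exact for affine/quadratic spectra on uniform grids and a standard
#' approximation on slowly varying grids such as a wavenumber-uniform
#' instrument grid reported in nm.
#'
#' @param x spectra matrix.
#' @param order derivative order, 1 or 2.
#' @param window odd filter window length (default 11).
#' @param polyorder local polynomial degree (default 2); must satisfy
#'   `window > polyorder >= order`.
#' @return differentiated spectra matrix of the same shape.
#' @export
derivative <- function(x, order = 1L, window = 11L, polyorder = 2L) {
  stopifnot(order %in% c(1L, 2L))
  if (window %% 2 == 0) stop("window must be odd")
  if (window > ncol(x)) stop("window larger than the number of bands")
  if (!(window > polyorder && polyorder >= order)) {
    stop("need window > polyorder >= order")
  }
  wl <- wavelengths(x)
  p_bands <- length(wl)
  # band-wise dλ/d(index) by central differences (one-sided at the ends)
  h <- c(wl[2] - wl[1], (wl[3:p_bands] - wl[1:(p_bands - 2)]) / 2,
         wl[p_bands] - wl[p_bands - 1])
  out <- t(apply(x, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = order, ts = 1))
  out <- sweep(out, 2, h^order, `/`)
  dimnames(out) <- dimnames(x)
  out
}

#' Pre-processing method dispatcher
#'
#' Applies one of the seven Block-I treatments by name: `raw`
#' (passthrough), `b.als`, `b.irls`, `msc`, `snv`, `d1`, `d2`. Extra
#' arguments are forwarded to the method. The spec used is recorded in
#' the output's `"preprocess"` attribute. Calibration and validation sets
#' are intended to be passed through this function separately; nothing is
#' cached between calls.
#'
#' @param x spectra matrix.
#' @param method method name (see above).
#' @param ... method parameters (e.g. `lambda`, `p`, `window`,
#'   `polyorder`, `reference`).
#' @return pre-processed spectra matrix.
#' @export
apply_preprocess <- function(x, method = c("raw", "b.als", "b.irls", "msc",
                                           "snv", "d1", "d2"), ...) {
  method <- match.arg(method)
  out <- switch(method,
    raw = x,
    b.als = baseline_als(x, ...),
    b.irls = baseline_irls(x, ...),
    msc = msc(x, ...),
    snv = snv(x),
    d1 = derivative(x, order = 1L, ...),
    d2 = derivative(x, order = 2L, ...)
  )
  attr(out, "preprocess") <- method
  out
}

#' @rdname apply_preprocess
#' @format NULL
#' @details `PREPROCESS_METHODS` lists the seven recognized method names.
#' @export
PREPROCESS_METHODS <- c("raw", "b.als", "b.irls", "msc", "snv", "d1", "d2")
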