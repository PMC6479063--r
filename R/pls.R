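#' Fit a PLS1 regression by NIPALS
#'
#' Mean-centered (no variance scaling) partial least squares with a single
#' response, computed by the NIPALS recursion: at each step the weight
#' vector is the covariance direction X'y (normalized), scores t = Xw,
#' loadings p = X't/t't, response loading q = y't/t't, followed by
#' deflation of X and y. The regression coefficient vector on the original
#' bands is b = W (P'W)^{-1} q, with intercept y_mean - x_mean'b.
#'
#' If the residual X becomes (numerically) rank deficient before `nlv`
#' components are extracted, the fit stops early with a warning and the
#' effective number of components is reduced.
#'
#' @param X predictor matrix, n x p (bands in columns).
#' @param y numeric response vector of length n.
#' @param nlv number of latent variables (1 <= nlv <= min(n-1, p)).
#' @param band_indices optional indices of `X`'s columns in a wider grid,
#'   stored for bookkeeping when fitting on a wavelength subset.
#' @return object of class `pls_model` with elements `x_mean`, `y_mean`,
#'   `weights` (p x nlv), `loadings` (p x nlv), `q` (response loadings),
#'   `scores`, `coefficients`, `intercept`, `nlv` (effective), `fitted`,
#'   `band_indices`.
#' @export
fit_pls <- function(X, y, nlv, band_indices = seq_len(ncol(X))) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, !anyNA(X), !anyNA(y))
  nlv <- as.integer(nlv)
  if (nlv < 1) stop("nlv must be >= 1")
  if (nlv > min(n - 1, p)) {
    stop("nlv must be <= min(n_samples - 1, n_bands)")
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xd <- sweep(X, 2, x_mean)
  yd <- y - y_mean
  W <- P <- matrix(0, p, nlv)
  Tm <- matrix(0, n, nlv)
  q <- numeric(nlv)
  tol <- max(sum(Xd^2), .Machine$double.eps) * 1e-14
  h_eff <- 0L
  for (h in seq_len(nlv)) {
    w <- crossprod(Xd, yd)[, 1]
    wn <- sqrt(sum(w^2))
    if (wn^2 <= tol) {
      warning("rank deficiency: stopping at ", h_eff,
              " of ", nlv, " requested components")
      break
    }
    w <- w / wn
    t_h <- Xd %*% w
    tt <- sum(t_h^2)
    if (tt <= tol) {
      warning("rank deficiency: stopping at ", h_eff,
              " of ", nlv, " requested components")
      break
    }
    p_h <- crossprod(Xd, t_h)[, 1] / tt
    q_h <- sum(yd * t_h) / tt
    Xd <- Xd - t_h %*% t(p_h)
    yd <- yd - t_h * q_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
    h_eff <- h
  }
  if (h_eff == 0L) stop("no usable PLS component: X is centered to zero")
  W <- W[, seq_len(h_eff), drop = FALSE]
  P <- P[, seq_len(h_eff), drop = FALSE]
  Tm <- Tm[, seq_len(h_eff), drop = FALSE]
  q <- q[seq_len(h_eff)]
  b <- W %*% solve(crossprod(P, W), q)
  model <- structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                          loadings = P, q = q, scores = Tm,
                          coefficients = as.numeric(b),
                          intercept = y_mean - sum(x_mean * b),
                          nlv = h_eff, band_indices = band_indices),
                     class = "pls_model")
  model$fitted <- predict(model, X)
  model
}

#' Predict from a fitted PLS model
#'
#' Coefficient-form prediction: yhat = (X - x_mean) b + y_mean, identical
#' (to numerical precision) to propagating latent scores.
#'
#' @param object a `pls_model`.
#' @param newdata matrix with as many columns as the model was fit on.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " bands; model expects ",
         length(object$x_mean))
  }
  as.numeric(sweep(newdata, 2, object$x_mean) %*% object$coefficients +
               object$y_mean)
}

# Score-form predictions for every component count 1..nlv in one pass
# (used by cross-validation). Returns an n x nlv matrix.
predict_all_nlv <- function(model, newdata) {
  Xd <- sweep(as.matrix(newdata), 2, model$x_mean)
  n <- nrow(Xd); H <- model$nlv
  preds <- matrix(model$y_mean, n, H)
  acc <- rep(model$y_mean, n)
  for (h in seq_len(H)) {
    t_h <- Xd %*% model$weights[, h]
    acc <- acc + t_h * model$q[h]
    Xd <- Xd - t_h %*% t(model$loadings[, h])
    preds[, h] <- acc
  }
  preds
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS1 model (NIPALS): ", x$nlv, " latent variable(s), ",
      length(x$coefficients), " band(s)\n", sep = "")
  invisible(x)
}

#' Ten-fold cross-validated choice of the number of latent variables
#'
#' Samples are shuffled (seeded) into `folds` nearly equal folds; for
#' each fold a PLS model with `max_nlv` components is fit on the
#' remaining samples and held-out predictions are accumulated for every
#' candidate component count. RMSECV per candidate is the root mean
#' squared held-out error over all samples; the chosen nLV is the global
#' RMSECV minimizer, ties resolved toward the smaller count.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param max_nlv largest candidate nLV (default 15; automatically capped
#'   at what the smallest training fold supports).
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold shuffle; `NULL` uses the current RNG
#'   stream (for callers managing their own seeding).
#' @return list of class `cv_profile`: `rmsecv` (per candidate),
#'   `chosen_nlv`, `folds`, `fold_assignment`, `seed`.
#' @export
cross_validate_nlv <- function(X, y, max_nlv = 15L, folds = 10L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (folds > n) stop("more folds than samples")
  if (folds < 2) stop("folds must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  assign <- sample(rep(seq_len(folds), length.out = n))
  min_train <- n - max(table(assign))
  cap <- min(max_nlv, min_train - 1, ncol(X))
  if (cap < 1) stop("training folds too small for even 1 latent variable")
  pred <- matrix(NA_real_, n, cap)
  for (k in seq_len(folds)) {
    test <- which(assign == k)
    fit <- suppressWarnings(fit_pls(X[-test, , drop = FALSE], y[-test], cap))
    pk <- predict_all_nlv(fit, X[test, , drop = FALSE])
    if (fit$nlv < cap) {  # rank-deficient fold: pad with its last column
      pk <- cbind(pk, pk[, rep(fit$nlv, cap - fit$nlv), drop = FALSE])
    }
    pred[test, ] <- pk
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  # ties (including numerically indistinguishable minima, e.g. all ~0 on
  # noise-free data) resolve to the smallest component count
  tie_tol <- 1e-8 * max(rmsecv)
  chosen <- which(rmsecv <= min(rmsecv) + tie_tol)[1]
  structure(list(rmsecv = rmsecv, chosen_nlv = chosen,
                 folds = folds, fold_assignment = assign, seed = seed),
            class = "cv_profile")
}

#' Serialize a PLS model to a plain-list / JSON-ready structure
#'
#' Converts a fitted model to a list of plain numeric vectors (centering
#' vectors, per-component weights/loadings, coefficients, nLV, band
#' indices) that survives JSON or YAML round trips, and back. Reloaded
#' models predict identically.
#'
#' @param model a `pls_model`.
#' @param x a list produced by `pls_model_to_list()` (possibly after a
#'   JSON round trip).
#' @return `pls_model_to_list`: a named list; `pls_model_from_list`: a
#'   `pls_model`.
#' @export
pls_model_to_list <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  list(x_mean = unname(model$x_mean), y_mean = model$y_mean,
       weights = lapply(seq_len(ncol(model$weights)),
                        function(h) unname(model$weights[, h])),
       loadings = lapply(seq_len(ncol(model$loadings)),
                         function(h) unname(model$loadings[, h])),
       q = model$q, coefficients = unname(model$coefficients),
       intercept = model$intercept, nlv = model$nlv,
       band_indices = model$band_indices)
}

#' @rdname pls_model_to_list
#' @export
pls_model_from_list <- function(x) {
  need <- c("x_mean", "y_mean", "weights", "loadings", "q",
            "coefficients", "nlv", "band_indices")
  if (!all(need %in% names(x))) {
    stop("missing field(s): ", paste(setdiff(need, names(x)), collapse = ", "))
  }
  structure(list(x_mean = as.numeric(x$x_mean), y_mean = as.numeric(x$y_mean),
                 weights = do.call(cbind, lapply(x$weights, as.numeric)),
                 loadings = do.call(cbind, lapply(x$loadings, as.numeric)),
                 q = as.numeric(x$q),
                 coefficients = as.numeric(x$coefficients),
                 intercept = as.numeric(x$intercept),
                 nlv = as.integer(x$nlv),
                 band_indices = as.integer(x$band_indices)),
            class = "pls_model")
}
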