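#' Default component band library
#'
#' Gaussian absorption bands for the main chemical components of ground
#' root tissue in the NIR. Lignin carries bands at 1243, 1428, 1881 and
#' 2274 nm (aromatic/phenolic O-H and C-H overtones); the competing
#' components absorb at 1409 nm (wax, aliphatic C-H), 1715/1735 nm
#' (cellulose / polyoses C-H first overtones), and 2035/2437 nm (protein
#' amide and helix structures). Amplitudes are chosen so that the lignin
#' bands dominate the regression signal, which is what makes wavelength
#' selection on simulated mixtures a meaningful recovery test.
#'
#' @return data frame with columns `component`, `center` (nm), `width`
#'   (Gaussian sigma, nm), `amplitude` (absorbance units).
#' @export
default_band_library <- function() {
  lib <- data.frame(
    component = c("lignin", "lignin", "lignin", "lignin",
                  "wax", "cellulose", "polyoses", "protein", "protein"),
    center    = c(1243, 1428, 1881, 2274,
                  1409, 1715, 1735, 2035, 2437),
    width     = rep(25, 9),
    amplitude = c(0.9, 1.0, 1.1, 1.0,
                  0.35, 0.45, 0.40, 0.35, 0.30),
    stringsAsFactors = FALSE
  )
  lib
}

validate_bands <- function(bands, grid) {
  stopifnot(all(c("component", "center", "width", "amplitude") %in% names(bands)))
  ok_comp <- c("lignin", "cellulose", "polyoses", "protein", "wax", "water")
  if (!all(bands$component %in% ok_comp)) {
    stop("unknown component label(s): ",
         paste(setdiff(bands$component, ok_comp), collapse = ", "))
  }
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$amplitude < 0)) stop("band amplitudes must be >= 0")
  if (any(bands$center < min(grid) | bands$center > max(grid))) {
    stop("band center outside the wavelength grid range")
  }
  bands
}

#' Synthetic-study configuration
#'
#' Bundles everything the simulator needs: the wavelength grid, the
#' component band library, the lignin distribution (truncated normal,
#' matching the field study's mean 20.52 %, SD 7.7 %, observed range
#' [7.7, 42.8] %), the split of non-lignin mass among the other
#' components, and the distortion model (log-normal multiplicative
#' scatter, random polynomial baseline, additive band noise).
#'
#' @param n_samples number of samples to simulate (>= 2).
#' @param grid wavelength grid in nm (default [default_grid()]).
#' @param bands band library (default [default_band_library()]).
#' @param lignin_mean,lignin_sd truncated-normal parameters, in %.
#' @param lignin_bounds truncation bounds `c(lo, hi)` in %, inside (0, 100).
#' @param nonlignin_fractions named proportions (summing to 1) of the
#'   non-lignin mass assigned to cellulose, polyoses, protein, wax and
#'   residual.
#' @param composition_concentration Dirichlet concentration of the jitter
#'   around `nonlignin_fractions` (larger = tighter; `Inf` = no jitter).
#' @param scatter_sd log-scale SD of the per-sample multiplicative
#'   scatter factor.
#' @param baseline_degree,baseline_scale degree of the random polynomial
#'   baseline and SD of its coefficients (absorbance units).
#' @param noise_sd SD of additive Gaussian band noise (absorbance units)
#'   at the center of the spectral range.
#' @param noise_edge_gain factor by which the band-noise SD grows toward
#'   the ends of the wavelength range (quartic profile
#'   `1 + gain * u^4`, `u` in [-1, 1]); FT-NIR signal-to-noise degrades
#'   strongly at the edges of the working range where lamp output and
#'   detector response fall off. 0 = homoscedastic noise.
#' @param seed integer RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_samples = 120L,
                         grid = default_grid(),
                         bands = default_band_library(),
                         lignin_mean = 20.52,
                         lignin_sd = 7.7,
                         lignin_bounds = c(7.7, 42.8),
                         nonlignin_fractions = c(cellulose = 0.40,
                                                 polyoses = 0.20,
                                                 protein = 0.15,
                                                 wax = 0.10,
                                                 residual = 0.15),
                         composition_concentration = 50,
                         scatter_sd = 0.1,
                         baseline_degree = 4L,
                         baseline_scale = 0.1,
                         noise_sd = 0.02,
                         noise_edge_gain = 9,
                         seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (noise_edge_gain < 0) stop("noise_edge_gain must be >= 0")
  if (scatter_sd < 0) stop("scatter_sd must be >= 0")
  if (lignin_bounds[1] >= lignin_bounds[2] ||
      lignin_bounds[1] <= 0 || lignin_bounds[2] >= 100) {
    stop("lignin_bounds must be ordered and inside (0, 100)")
  }
  if (abs(sum(nonlignin_fractions) - 1) > 1e-9) {
    stop("nonlignin_fractions must sum to 1")
  }
  check_grid(grid)
  validate_bands(bands, grid)
  structure(list(n_samples = as.integer(n_samples), grid = grid,
                 bands = bands, lignin_mean = lignin_mean,
                 lignin_sd = lignin_sd, lignin_bounds = lignin_bounds,
                 nonlignin_fractions = nonlignin_fractions,
                 composition_concentration = composition_concentration,
                 scatter_sd = scatter_sd,
                 baseline_degree = as.integer(baseline_degree),
                 baseline_scale = baseline_scale, noise_sd = noise_sd,
                 noise_edge_gain = noise_edge_gain,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Truncated-normal sampling by rejection: exact and simple for the mild
# truncation used here (bounds ~1.7 SD from the mean).
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Draw per-sample chemical compositions
#'
#' Lignin content is drawn from the configured truncated normal; the
#' remaining mass (100 - lignin) is split among cellulose, polyoses,
#' protein, wax and residual by Dirichlet jitter around the configured
#' base fractions. Every row sums to exactly 100.
#'
#' @param cfg a [synth_config()].
#' @return data frame with columns `sample_id`, `lignin`, `cellulose`,
#'   `polyoses`, `protein`, `wax`, `residual` (all in %).
#' @export
sample_compositions <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  lignin <- rtruncnorm_reject(n, cfg$lignin_mean, cfg$lignin_sd,
                              cfg$lignin_bounds[1], cfg$lignin_bounds[2])
  base <- cfg$nonlignin_fractions
  conc <- cfg$composition_concentration
  if (is.finite(conc)) {
    g <- matrix(stats::rgamma(n * length(base),
                              shape = rep(base * conc, each = n)),
                nrow = n)
    shares <- g / rowSums(g)
  } else {
    shares <- matrix(base, nrow = n, ncol = length(base), byrow = TRUE)
  }
  colnames(shares) <- names(base)
  comp <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     lignin = lignin,
                     shares * (100 - lignin),
                     stringsAsFactors = FALSE)
  # force exact closure against float drift
  tot <- rowSums(comp[, -1])
  comp$residual <- comp$residual + (100 - tot)
  comp
}

# Component pure-absorbance profiles on the grid: each component's
# spectrum is the sum of its Gaussian bands at unit (100 %) content.
component_profiles <- function(cfg) {
  comps <- c("lignin", "cellulose", "polyoses", "protein", "wax", "residual")
  prof <- matrix(0, nrow = length(comps), ncol = length(cfg$grid),
                 dimnames = list(comps, NULL))
  for (k in seq_len(nrow(cfg$bands))) {
    b <- cfg$bands[k, ]
    prof[b$component, ] <- prof[b$component, ] +
      b$amplitude * exp(-0.5 * ((cfg$grid - b$center) / b$width)^2)
  }
  prof
}

#' Simulate a spectra + reference dataset
#'
#' Beer-Lambert linear mixing: each sample's pure spectrum is the
#' content-weighted sum of the component profiles; distortions are then
#' applied in order — a per-sample log-normal multiplicative scatter
#' factor, a random polynomial baseline, and i.i.d. Gaussian band noise.
#' Deterministic for a fixed config (the composition draw and the
#' distortion draw share the config seed stream).
#'
#' @param cfg a [synth_config()].
#' @param compositions optional composition table; when omitted it is
#'   drawn via [sample_compositions()] (the usual entry point).
#' @return list with `spectra` (absorbance matrix), `reference` (data
#'   frame `sample_id, lignin_pct`), `compositions`, and `pure` (the
#'   undistorted mixture spectra).
#' @export
simulate_spectra <- function(cfg, compositions = NULL) {
  if (is.null(compositions)) {
    compositions <- sample_compositions(cfg)  # seeds the stream
  } else {
    set.seed(cfg$seed)
  }
  comp_cols <- c("lignin", "cellulose", "polyoses", "protein", "wax", "residual")
  stopifnot(all(comp_cols %in% names(compositions)))
  cmat <- as.matrix(compositions[, comp_cols]) / 100
  if (any(cmat < 0)) stop("negative composition fraction")
  if (any(abs(rowSums(cmat) - 1) > 1e-9)) stop("composition rows must sum to 100")
  prof <- component_profiles(cfg)
  pure <- cmat %*% prof
  n <- nrow(pure); p <- ncol(pure)
  m <- exp(stats::rnorm(n, 0, cfg$scatter_sd))
  x01 <- seq(-1, 1, length.out = p)
  bl_coef <- matrix(stats::rnorm(n * (cfg$baseline_degree + 1),
                                 0, cfg$baseline_scale), nrow = n)
  baseline <- bl_coef %*% t(outer(x01, 0:cfg$baseline_degree, `^`))
  edge <- cfg$noise_edge_gain %||% 0
  noise_prof <- cfg$noise_sd * (1 + edge * x01^4)
  noise <- matrix(stats::rnorm(n * p, 0, 1), nrow = n) *
    rep(noise_prof, each = n)
  spectra <- as_spectra(m * pure + baseline + noise, cfg$grid,
                        compositions$sample_id)
  list(spectra = spectra,
       reference = data.frame(sample_id = compositions$sample_id,
                              lignin_pct = compositions$lignin,
                              stringsAsFactors = FALSE),
       compositions = compositions,
       pure = as_spectra(pure, cfg$grid, compositions$sample_id))
}

#' Simulate UV absorbance readings for a known lignin content
#'
#' Inverts the wet-chemistry arithmetic to build replicate fixtures: the
#' noise-free SAC is the calibration-curve inverse of `lignin_pct`, the
#' blank OD is fixed, and the sample OD is back-computed with dilution
#' factor F = 50 and the stated dry weight; Gaussian noise is added to
#' the sample OD readings.
#'
#' @param lignin_pct true lignin content in [0, 100] %.
#' @param curve calibration curve (default [default_curve()]).
#' @param noise_sd SD of the OD reading noise (>= 0).
#' @param n_reps number of replicate readings (2-4 recommended).
#' @param seed RNG seed.
#' @param od_b blank optical density (default 0.05).
#' @param w_d sample dry weight in mg (default 10).
#' @param f dilution factor (default 50).
#' @return data frame `replicate_id, OD_S, OD_B, W_d_mg, F`.
#' @export
simulate_absorbance_readings <- function(lignin_pct, curve = default_curve(),
                                         noise_sd = 0, n_reps = 3L, seed = 1L,
                                         od_b = 0.05, w_d = 10, f = 50) {
  if (lignin_pct < 0 || lignin_pct > 100) stop("lignin_pct must be in [0, 100]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  sac <- lignin_to_sac(lignin_pct, curve)
  od_s <- od_b + sac * w_d / f + stats::rnorm(n_reps, 0, noise_sd)
  data.frame(replicate_id = seq_len(n_reps), OD_S = od_s, OD_B = od_b,
             W_d_mg = w_d, F = f)
}
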