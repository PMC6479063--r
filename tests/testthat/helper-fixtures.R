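# Small in-code fixtures shared across test files.

# A tiny spectra matrix on a uniform grid, seeded.
tiny_spectra <- function(n = 5, p = 10, seed = 42, wl = seq(1000, 1090, 10)) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%d", 1:n), sprintf("%.6g", wl)))
  m
}

# Small synthetic study used by several modules: cheap but full-structure.
small_study <- function(n = 60, seed = 3, ...) {
  cfg <- synth_config(n_samples = n, seed = seed, ...)
  simulate_spectra(cfg)
}

# Gaussian peak plus polynomial baseline on a unit grid, for the
# baseline-correction fixtures.
peak_fixture <- function(p = 300, center = 150, sigma = 12, height = 1,
                         bl_coefs = c(0.5, 0.3, -0.2)) {
  x <- seq(-1, 1, length.out = p)
  peak <- height * exp(-0.5 * ((seq_len(p) - center) / sigma)^2)
  baseline <- drop(outer(x, seq_along(bl_coefs) - 1, `^`) %*% bl_coefs)
  list(y = peak + baseline, peak = peak, baseline = baseline)
}
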