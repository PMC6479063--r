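#' Default FT-NIR wavelength grid
#'
#' Builds the 662-point grid used throughout the package: uniform in
#' wavenumber from 12489 to 3594 cm^-1 inclusive (the working range of a
#' bench FT-NIR analyzer at 8 cm^-1 resolution), reported in nanometres
#' and returned in ascending wavelength order.
#'
#' @param n_points number of spectral bands (default 662).
#' @param wn_max,wn_min wavenumber range in cm^-1 (defaults 12489 and 3594).
#' @return numeric vector of wavelengths in nm, strictly increasing.
#' @export
default_grid <- function(n_points = 662L, wn_max = 12489, wn_min = 3594) {
  stopifnot(n_points >= 3L, wn_max > wn_min, wn_min > 0)
  wn <- seq(wn_max, wn_min, length.out = n_points)
  sort(1e7 / wn)
}

#' Wavelengths of a spectra matrix
#'
#' Spectra are stored as plain numeric matrices (rows = samples, columns =
#' bands) whose column names carry the wavelength grid in nm; this reads
#' them back as numbers and validates the grid.
#'
#' @param x spectra matrix with numeric wavelength column names.
#' @return numeric vector of wavelengths (nm).
#' @export
wavelengths <- function(x) {
  wl <- suppressWarnings(as.numeric(colnames(x)))
  if (is.null(colnames(x)) || anyNA(wl)) {
    stop("spectra matrix must have numeric wavelength column names")
  }
  wl
}

# Internal constructor: attach grid + sample ids and validate invariants.
as_spectra <- function(abs_matrix, grid, sample_ids = NULL) {
  abs_matrix <- as.matrix(abs_matrix)
  if (length(grid) != ncol(abs_matrix)) {
    stop("grid length (", length(grid), ") != number of bands (",
         ncol(abs_matrix), ")")
  }
  check_grid(grid)
  if (anyNA(abs_matrix)) stop("spectra matrix contains missing values")
  colnames(abs_matrix) <- format_grid(grid)
  if (!is.null(sample_ids)) rownames(abs_matrix) <- as.character(sample_ids)
  abs_matrix
}

check_grid <- function(grid) {
  if (length(grid) < 3L) stop("wavelength grid must have at least 3 points")
  d <- diff(grid)
  if (any(d == 0)) stop("duplicated wavelengths in grid")
  if (any(d < 0)) {
    stop("wavelength grid must be strictly increasing; ",
         "sort columns in ascending nm order before loading")
  }
  invisible(grid)
}

format_grid <- function(grid) sprintf("%.10g", grid)
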