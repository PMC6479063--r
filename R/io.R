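#' Convert transmission spectra to absorbance
#'
#' FT-NIR instruments in transmission mode record T in (0, 1]; absorbance
#' is A = log10(1/T). Values above 1 are physically suspect (stray light,
#' reference drift) and are flagged with a warning but converted anyway;
#' values <= 0 have no finite absorbance and are an error.
#'
#' @param tr transmission matrix (rows = samples, columns = bands,
#'   wavelength column names as in [wavelengths()]).
#' @return absorbance matrix of the same shape.
#' @export
to_absorbance <- function(tr) {
  tr <- as.matrix(tr)
  bad <- which(tr <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-positive transmission at sample %s, band %s",
                 rownames(tr)[bad[1, 1]] %||% bad[1, 1],
                 colnames(tr)[bad[1, 2]] %||% bad[1, 2]))
  }
  if (any(tr > 1)) {
    warning(sum(tr > 1), " transmission values > 1 flagged (kept)")
  }
  log10(1 / tr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average replicate spectra per sample
#'
#' Bench protocol: each sample is poured, measured, shaken and re-measured
#' several times (five in routine use) and the replicate spectra averaged
#' band-wise to capture repacking variability.
#'
#' @param x spectra matrix containing all replicate rows.
#' @param sample_ids character/factor of length `nrow(x)` mapping each
#'   replicate row to its sample.
#' @param expected_reps replicate count that does not trigger a warning
#'   (default 5).
#' @return spectra matrix with one averaged row per sample (order of first
#'   appearance); attribute `"replicate_counts"` records counts.
#' @export
average_replicate_spectra <- function(x, sample_ids, expected_reps = 5L) {
  stopifnot(length(sample_ids) == nrow(x))
  ids <- factor(sample_ids, levels = unique(as.character(sample_ids)))
  counts <- as.integer(table(ids))
  if (any(counts != expected_reps)) {
    warning("replicate counts differ from ", expected_reps, " for: ",
            paste(levels(ids)[counts != expected_reps], collapse = ", "))
  }
  out <- rowsum(x, ids, reorder = FALSE) / counts
  rownames(out) <- levels(ids)
  attr(out, "replicate_counts") <- stats::setNames(counts, levels(ids))
  out
}

#' Read / write the spectra CSV interchange format
#'
#' The interchange format is UTF-8 comma-separated text: an optional
#' leading comment line `# unit: nm` or `# unit: cm-1`, then a header row
#' `sample_id,<wl_1>,...,<wl_p>` with wavelengths as numeric column names,
#' then one row per sample. Wavelengths must be strictly increasing (in
#' nm); a cm-1 header is converted via lambda(nm) = 1e7 / nu(cm-1) and the
#' columns re-ordered to ascending nm. Values are written with 17
#' significant digits so a write/read round trip is exact in double
#' precision.
#'
#' @param path file path.
#' @param x spectra matrix (for the writer).
#' @param unit unit recorded in the file comment (`"nm"` or `"cm-1"`).
#' @return `read_spectra`: a spectra matrix; `write_spectra`: `path`,
#'   invisibly.
#' @export
read_spectra <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  unit <- "nm"
  if (length(lines) && grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("unit:\\s*(\\S+)", lines[1]))[[1]]
    if (length(m) == 2) unit <- m[2]
    lines <- lines[-1]
  }
  if (length(lines) < 2) stop("spectra file needs a header and >=1 sample row")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 4 || header[1] != "sample_id") {
    stop("spectra header must be 'sample_id,<wavelengths...>'")
  }
  wl <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wl)) stop("non-numeric wavelength in header")
  if (anyDuplicated(wl)) stop("duplicated wavelength column in header")
  if (unit == "cm-1") wl <- 1e7 / wl
  if (is.unsorted(wl, strictly = TRUE)) {
    ord <- order(wl)
    if (unit == "nm") {
      stop("wavelength header not strictly increasing; ",
           "write the grid in ascending nm order")
    }
    wl <- wl[ord]
  } else {
    ord <- seq_along(wl)
  }
  body <- strsplit(lines[-1], ",", fixed = TRUE)
  widths <- lengths(body)
  if (any(widths != length(header))) {
    stop("ragged row(s): ", paste(which(widths != length(header)), collapse = ", "))
  }
  ids <- vapply(body, `[`, "", 1L)
  vals <- vapply(body, function(r) {
    v <- suppressWarnings(as.numeric(r[-1]))
    if (anyNA(v)) stop("non-numeric absorbance value in row for sample ", r[1])
    v
  }, numeric(length(wl)))
  as_spectra(t(vals)[, ord, drop = FALSE], wl, ids)
}

#' @rdname read_spectra
#' @export
write_spectra <- function(x, path, unit = "nm") {
  wl <- wavelengths(x)
  header <- paste(c("sample_id", sprintf("%.17g", wl)), collapse = ",")
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i] %||% i, sprintf("%.17g", x[i, ])), collapse = ",")
  }, "")
  writeLines(c(sprintf("# unit: %s", unit), header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read / write reference lignin tables
#'
#' Two-column CSV `sample_id,lignin_pct` pairing each spectrum with its
#' wet-chemistry lignin content (% of dry mass).
#'
#' @param path file path.
#' @param ref data frame with columns `sample_id` and `lignin_pct`.
#' @export
read_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "lignin_pct") %in% names(ref))) {
    stop("reference CSV needs columns sample_id, lignin_pct")
  }
  if (!is.numeric(ref$lignin_pct) || anyNA(ref$lignin_pct)) {
    stop("lignin_pct must be numeric and complete")
  }
  ref
}

#' @rdname read_reference
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(ref[, c("sample_id", "lignin_pct")], path, row.names = FALSE)
  invisible(path)
}
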