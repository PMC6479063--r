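#' Acetyl-bromide lignin quantification arithmetic
#'
#' Acetyl bromide in glacial acetic acid solubilizes lignin from <= 10 mg
#' ground-tissue samples; UV optical density at 280 nm, blank-corrected and
#' scaled by the dilution factor per mg sample, gives the specific
#' absorption coefficient
#'
#'   SAC = (OD_S - OD_B) * F / W_d   (mL cm^-1 mg^-1)
#'
#' with a 1 cm quartz cuvette path assumed throughout. A linear calibration
#' against purified lignin standards then converts SAC to lignin content as
#' a percent of dry mass:
#'
#'   L = (SAC - intercept) * 100 / slope_denominator
#'
#' with default intercept 0.05 and slope denominator 13.06 (SAC units per
#' 100 % lignin).
#'
#' @param od_s optical density of the sample (dimensionless).
#' @param od_b optical density of the blank.
#' @param w_d sample dry weight in mg (> 0).
#' @param f dilution factor in mL mg^-1 (default 50).
#' @param d cuvette path length in cm (default 1; kept explicit so the
#'   assumption is visible, the printed formula does not use it).
#' @return SAC value(s), vectorized over the inputs.
#' @export
compute_sac <- function(od_s, od_b, w_d, f = 50, d = 1) {
  if (any(w_d <= 0)) stop("sample weight w_d must be > 0")
  if (any(f <= 0)) stop("dilution factor f must be > 0")
  if (any(d <= 0)) stop("path length d must be > 0")
  if (any(od_s < od_b)) {
    warning("OD_S < OD_B for some reading(s): negative SAC returned")
  }
  (od_s - od_b) * f / w_d
}

#' Pool replicate SAC determinations
#'
#' Each sample is digested and read 2-4 times (on different days); the
#' per-sample SAC is the arithmetic mean of the replicates.
#'
#' @param sacs numeric vector of replicate SAC values (>= 1).
#' @return list with `replicate_sacs`, `sample_sac` (mean) and `n`.
#' @export
average_replicates <- function(sacs) {
  if (length(sacs) == 0) stop("no replicate SAC values supplied")
  if (length(sacs) < 2 || length(sacs) > 4) {
    warning("replicate count ", length(sacs), " outside the expected 2-4 range")
  }
  list(replicate_sacs = sacs, sample_sac = mean(sacs), n = length(sacs))
}

#' Default SAC-to-lignin calibration curve
#'
#' @param intercept SAC at zero lignin (default 0.05).
#' @param slope_denominator SAC units per 100 % lignin (default 13.06).
#' @return calibration curve object (class `lignin_curve`).
#' @export
default_curve <- function(intercept = 0.05, slope_denominator = 13.06) {
  if (slope_denominator <= 0) stop("slope_denominator must be > 0")
  structure(list(intercept = intercept, slope_denominator = slope_denominator),
            class = "lignin_curve")
}

#' Convert SAC to lignin content
#'
#' Applies the linear calibration L = (SAC - intercept) * 100 /
#' slope_denominator. Out-of-range results (L < 0 or L > 100) are possible
#' for noisy readings; they are returned unclipped with an attribute flag
#' so QC can act on them.
#'
#' @param sac SAC value(s).
#' @param curve calibration curve from [default_curve()] or
#'   [fit_calibration_curve()].
#' @return lignin content in % dry mass, with attribute `out_of_range`
#'   (logical vector) when any value falls outside [0, 100].
#' @export
sac_to_lignin <- function(sac, curve = default_curve()) {
  l <- (sac - curve$intercept) * 100 / curve$slope_denominator
  oor <- l < 0 | l > 100
  if (any(oor)) attr(l, "out_of_range") <- oor
  l
}

# Inverse of sac_to_lignin; used by the simulator to build fixtures.
lignin_to_sac <- function(lignin_pct, curve = default_curve()) {
  curve$intercept + curve$slope_denominator * lignin_pct / 100
}

#' Fit a SAC calibration curve from lignin standards
#'
#' Dilution series of purified lignin (known amounts, measured SAC) are
#' fitted by ordinary least squares SAC = intercept + slope * amount. The
#' amount axis is expressed as a mass fraction in [0, 1], so the returned
#' `slope_denominator` (SAC per 100 % lignin) equals the fitted slope.
#'
#' @param amount lignin amounts of the standards, as fractions in [0, 1].
#' @param sac measured SAC of each standard.
#' @return `lignin_curve` with `intercept`, `slope_denominator`, and the
#'   underlying `lm` fit as attribute `"fit"`.
#' @export
fit_calibration_curve <- function(amount, sac) {
  stopifnot(length(amount) == length(sac))
  if (length(amount) < 3) stop("need >= 3 calibration standards")
  if (diff(range(amount)) <= 0) stop("standards must span a range of amounts")
  fit <- stats::lm(sac ~ amount)
  curve <- default_curve(intercept = unname(stats::coef(fit)[1]),
                         slope_denominator = unname(stats::coef(fit)[2]))
  attr(curve, "fit") <- fit
  curve
}

#' Pooled spread of replicate lignin determinations
#'
#' Summarizes replicate-to-replicate variability of the wet-chemistry
#' assay across samples. The default is the pooled standard deviation of
#' replicate lignin values (square root of the replicate-variance pooled
#' over samples with their within-sample degrees of freedom); the
#' `"se_mean"` variant divides each sample's contribution by its replicate
#' count first, giving a pooled standard error of the sample means.
#'
#' @param lignin_tbl data frame with columns `sample_id` and `lignin_pct`,
#'   one row per replicate determination.
#' @param variant `"pooled_sd"` (default) or `"se_mean"`.
#' @return pooled spread in lignin % units.
#' @export
replicate_spread <- function(lignin_tbl, variant = c("pooled_sd", "se_mean")) {
  variant <- match.arg(variant)
  stopifnot(all(c("sample_id", "lignin_pct") %in% names(lignin_tbl)))
  sp <- split(lignin_tbl$lignin_pct, lignin_tbl$sample_id)
  sp <- sp[lengths(sp) >= 2]
  if (length(sp) == 0) stop("no sample has >= 2 replicates")
  ss <- vapply(sp, function(v) sum((v - mean(v))^2), 0)
  df <- vapply(sp, function(v) length(v) - 1, 0)
  if (variant == "se_mean") ss <- ss / lengths(sp)
  sqrt(sum(ss) / sum(df))
}

#' Lignin reference table from a replicate-readings CSV
#'
#' Reads `sample_id, replicate_id, OD_S, OD_B, W_d_mg, F` rows, computes
#' per-replicate SAC, averages replicates per sample and converts to
#' lignin content.
#'
#' @param path replicates CSV path.
#' @param curve calibration curve (default [default_curve()]).
#' @return data frame `sample_id, lignin_pct, n_replicates`.
#' @export
wetchem_reference <- function(path, curve = default_curve()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "replicate_id", "OD_S", "OD_B", "W_d_mg", "F")
  if (!all(need %in% names(df))) {
    stop("replicates CSV needs columns: ", paste(need, collapse = ", "))
  }
  df$sac <- compute_sac(df$OD_S, df$OD_B, df$W_d_mg, df$F)
  per <- lapply(split(df, df$sample_id), function(s) {
    est <- average_replicates(s$sac)
    data.frame(sample_id = s$sample_id[1],
               lignin_pct = as.numeric(sac_to_lignin(est$sample_sac, curve)),
               n_replicates = est$n)
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out[order(match(out$sample_id, unique(df$sample_id))), , drop = FALSE]
}
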