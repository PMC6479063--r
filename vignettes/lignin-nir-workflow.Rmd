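---
title: "Predicting fine-root lignin from NIR spectra: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fine-root lignin from NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Root lignin drives root decomposition and hence belowground carbon
turnover, but quantifying it by wet chemistry is slow. The acetyl-bromide
(AcBr) assay solubilizes lignin from ≤ 10 mg of ground root tissue and
reads it as UV optical density at 280 nm; near-infrared (NIR) spectra of
the same powders can then be calibrated against those reference values so
that lignin in new samples is predicted photometrically in seconds. This
package implements that chemometric chain end to end:

1. **Wet chemistry arithmetic** — specific absorption coefficient
   `SAC = (OD_S − OD_B)·F / W_d` (blank-corrected optical density times
   the dilution factor `F = 50` mL mg⁻¹ per mg dry sample, 1 cm cuvette),
   replicate pooling, and the linear calibration
   `L = (SAC − 0.05)·100 / 13.06` in % dry mass.
2. **Spectral pre-processing** — raw passthrough, asymmetric least
   squares (`b.als`) and iteratively restricted (`b.irls`) baseline
   removal, multiplicative scatter correction (MSC), standard normal
   variate (SNV), and Savitzky–Golay first/second derivatives.
3. **PLS1 regression** (NIPALS) with ten-fold cross-validated choice of
   the number of latent variables (nLV).
4. **CARS wavelength selection** — competitive adaptive reweighted
   sampling wrapped around the PLS core.
5. **Repeated outer validation** — seeded random calibration/validation
   splits, strictly separate pre-processing of the two sets, and the
   standard accuracy measures RMSEP, SEP, BIAS, R²p and RPD.
6. **A Beer–Lambert mixture simulator** that generates spectra +
   reference tables with the statistical structure of a real root
   dataset, so every stage is testable without external data.

# The regression engine

`fit_pls()` is PLS1 by the NIPALS recursion on mean-centered data (no
variance scaling — the chemometric convention for absorbance spectra,
where the measurement scale is already common across bands). Weight
vectors are the normalized covariance directions `X'y`; scores, loadings
and response loadings follow, with deflation after each component. The
coefficient form `b = W (P'W)⁻¹ q` is exposed and agrees with the
score-propagation form to 10⁻¹⁰; with `nLV = rank(X)` the fit reproduces
the ordinary-least-squares solution, which the tests use as an
independent oracle.

`cross_validate_nlv()` shuffles samples into ten folds (seeded), fits
each fold's complement once with the maximum candidate count and reads
off held-out predictions for every smaller count in the same pass.
The chosen nLV is the global RMSECV minimizer; ties — including
numerically indistinguishable minima, e.g. all ≈ 0 on noise-free data —
resolve to the smaller count. The search cap defaults to `max_nlv = 15`,
a safe ceiling given that repeated-validation means of selected nLV in
comparable root-spectroscopy work sit between 5 and 8; the one-standard-
error rule was deliberately not used because fractional mean nLV across
repeated splits indicates plain minimization in the work this mirrors.

# CARS

Each sampling run `i` of `N = 50`:

1. Draw `mc_ratio = 0.8` of the calibration samples (Monte Carlo).
2. Fit PLS on the currently retained bands of that subset; take
   normalized `|b|` as band weights. The component count for these fits
   is fixed **once, up front**, by ten-fold CV on the full calibration
   spectra. This matters: if the weight fits instead use the largest
   component count the data admit, the coefficients are essentially
   noise and the sampler selects noise-aligned bands whose inner RMSECV
   is optimistic — selection then *hurts* validation accuracy.
3. Forced removal: keep the top `⌈r_i · p⌉` bands by weight, where the
   exponentially decreasing function `r_i = (p/2)^((1−i)/(N−1))` runs
   from `r_1 = 1` to `r_N = 2/p` (this power form is algebraically the
   textbook `a·e^(−k·i)` but endpoint-exact in floating point). The
   target is clamped to the current retained-set size, since step 4 can
   shrink a set below the next run's target.
4. Adaptive reweighted sampling: `p` draws with replacement,
   probability ∝ weight, among the survivors; the distinct drawn indices
   form the next retained set. Drawing `p` times (not `⌈r_i·p⌉` times)
   keeps the EDF in charge of the retention schedule while ARS
   competitively drops low-weight survivors; drawing only the EDF target
   compounds the unique-draw shrinkage (≈ 0.63 per run) and collapses
   the set to 2 bands within a dozen runs.
5. Record the ten-fold RMSECV (CV-chosen nLV, capped) of a PLS model on
   the full calibration set restricted to the new retained set.

The best subset is the retained set of the run with minimal RMSECV; ties
go to the smaller subset, then the earlier run. Retained sets are
clamped below at 2 bands. For reporting, `cluster_adjacent()` groups a
selected subset into runs of adjacent grid indices — the "wavelength
cluster" reading used when interpreting selections chemically; the
adjacency gap is a reporting convention (default: strictly adjacent).

# Validation engine

`make_splits()` draws seeded random partitions (default 44:30 proportion
of calibration to validation) and persists per-repeat seeds derived from
one master seed, so full-spectrum and CARS runs consume byte-identical
plans and any repeat can be replayed bitwise. `evaluate_split()`
pre-processes the calibration and validation sets **independently** —
the operational convention for a deployed model meeting unknown samples —
then selects (optionally), cross-validates and fits on the calibration
set only. MSC is the instructive case: its reference defaults to the
mean spectrum of the set being processed, so separately processed sets
are corrected against different references and accuracy degrades
erratically across random splits, exactly the failure mode observed with
field spectra; a fixed-reference mode is available for operational use.

Metrics, with `e = predicted − observed` on the validation set:
`BIAS = mean(e)`; `RMSEP = √mean(e²)`;
`SEP = √(Σ(e − BIAS)²/(n−1))` (bias-corrected, n−1 denominator, which
makes `RMSEP² = SEP²·(n−1)/n + BIAS²` an exact identity);
`R²p` = squared Pearson correlation of predicted and observed (the
`1 − SSE/SST` variant is selectable); `RPD = sd(observed)/SEP`, so
`RPD·SEP = sd(observed)` exactly. BIAS is signed so that systematic
under-prediction is negative. RPD floors follow the usual reading:
\> 1.5–2 useful for screening, > 2–2.5 acceptable, > 2.5–3 good.

The survey summarizer reports column-wise min, quartiles, median and max
with type-7 (linear-interpolation) quantiles and per-column non-missing
counts. The shipped survey table under `extdata/` is **synthetic** — it
has the shape and missingness pattern of a real literature survey but
invented numbers, and is there to exercise the code path.

# The simulator: what it emulates, and what it does not

Spectra are Beer–Lambert mixtures: each sample's pure spectrum is the
content-weighted sum of component profiles, each profile a sum of
Gaussian bands (σ = 25 nm) on a 662-point grid uniform in wavenumber
from 12489 to 3594 cm⁻¹ (800–2782 nm) — the spacing choice is declared,
not inferred, since only the instrument's range, resolution and band
count are pinned down. The component library places lignin bands at
1243, 1428, 1881 and 2274 nm (amplitudes 0.9–1.1) and anti-correlated
component bands at 1409 (wax), 1715 (cellulose), 1735 (polyoses), 2035
and 2437 nm (protein, amplitudes 0.30–0.45): the wavelengths are the
chemically assigned cluster positions from root-spectroscopy work, and
the lignin amplitudes dominate so that wavelength selection has a
recoverable target.

Lignin content is truncated-normal, N(20.52, 7.7²) on [7.7, 42.8] %,
sampled by rejection (exact for this mild truncation). Note the
asymmetric truncation puts the distribution mean at 21.28 %, not at the
nominal 20.52 %. The non-lignin mass is split
cellulose/polyoses/protein/wax/residual = 40/20/15/10/15 % with
Dirichlet jitter (concentration 50) — plausible plant-tissue
proportions; the split is configurable and its closure (rows sum to
exactly 100) is enforced.

Distortions, in order: a per-sample log-normal multiplicative scatter
factor (`scatter_sd = 0.1`), a random polynomial baseline
(degree 4, coefficient SD `baseline_scale = 0.1` AU), and additive
Gaussian band noise with SD `noise_sd = 0.02` AU at mid-range growing
quartically to 10× at the range edges (`noise_edge_gain = 9`) — FT-NIR
signal-to-noise degrades strongly where lamp output and detector
response roll off. The noise and baseline scales were fixed by anchoring
the simulator to the *difficulty* of the real fine-root study this
mirrors: under the study geometry (44:30 splits), full-spectrum SNV-PLSR
on the default configuration validates at RPD ≈ 1.9 / RMSEP ≈ 4 % —
the published full-spectrum operating point — and a subset restricted
to the true band centers clearly beats the full spectrum, which is the
published direction of the selection gain. Those two anchors were fixed
before the CARS comparison was ever measured.

What the simulator does **not** emulate: radiative-transfer/particle-
size scattering physics, water-vapor lines, reference-value measurement
error in the lignin column (the reference table is the true mixing
content), species identity or richness structure, and instrument drift.
Consequently, passing recovery tests here shows the pipeline's
statistical machinery works under realistic spectral nuisance — it does
not certify accuracy on any particular real instrument or tissue. Two
visible consequences of the simplifications: the Block-I ranking of
pre-processing methods differs from field data (the polynomial baseline
model flatters the baseline correctors, and heavy edge noise penalizes
SNV's per-spectrum SD estimate and second derivatives), and
cross-validated nLV tends to run lower than on field spectra.

# Numerical choices

* Baseline correctors are Whittaker-type smoothers (second-difference
  penalty, sparse banded solves). `b.als`: λ = 10⁶, asymmetry p = 0.05,
  ≤ 10 reweighting iterations, with a tie guard (10⁻⁷ of the signal
  scale) so solver rounding cannot flip weights indefinitely; a
  non-converged weight set returns the current estimate with a warning.
  `b.irls`: same penalty, smooth logistic down-weighting
  `1/(1 + exp(6(r/s − 0.5)))` of points far above the baseline.
  On a Gaussian-peak-plus-polynomial fixture both preserve peak height
  within 5 % and recover the baseline within 5 % of the peak height.
* Derivatives are Savitzky–Golay (window 11, polynomial order 2,
  configurable), computed along the band index and scaled by the local
  dλ/d(index); exact for affine spectra on uniform grids, standard
  approximation on the slowly varying instrument grid.
* SNV uses the n−1 SD denominator; a constant spectrum is an error
  naming the sample.
* CSV spectra are written with 17 significant digits so write→read
  round trips are bit-exact; wavelength headers may be in nm or cm⁻¹
  (converted via λ = 10⁷/ν and re-ordered to ascending nm).
* All stochastic steps (composition draw, distortions, splits, CV
  folds, Monte-Carlo sampling, ARS) derive from explicit integer seeds;
  identical seeds replay every table bitwise.

# Problem sizes used in tests and scripts

The test suite and the acceptance script run the study at n = 120
samples with 71/49 splits (the 44:30 proportion), 25 validation repeats
for the accuracy comparisons and 100 repeats for the selection-frequency
profile; the wavelength-recovery experiment switches the baseline off so
that far-from-band wavelengths are uninformative by construction (with a
smooth baseline present, edge bands acquire genuine nuisance-correction
value and are legitimately selected). These sizes keep a full run on one
CPU in minutes while leaving the Monte-Carlo error of the compared means
well below the effects being checked.

# Known limitations

* `b.irls` implements the generic "penalized smoother with restricted
  reweighting" contract; it is not parameter-compatible with any
  specific legacy implementation.
* The CARS inner RMSECV is computed on the same calibration set the
  subsets were selected from, so it is an optimistic estimate of subset
  quality (inherent to the algorithm); outer validation is the honest
  measure.
* PLS2 (multivariate response), kernel PLS, coefficient uncertainty
  intervals, and alternative selectors (GA, SPA, IRIV) are out of scope.
* No vendor binary formats; CSV is the interchange contract.
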