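#' Acquisition protocol for a multi-TE diffusion series
#'
#' Bundles the fixed experimental geometry of a diffusion-weighted
#' acquisition: the b-value ladder, the echo-time series, the repetition
#' time and the number of signal averages. Gradient timings (delta, Delta)
#' can be attached per TE but are carried as metadata only; they never enter
#' any computation.
#'
#' @param b_values Numeric vector of diffusion weightings in s/mm^2.
#'   Must be strictly increasing, non-negative and contain 0.
#' @param te_values Numeric vector of echo times in ms, strictly increasing,
#'   all positive.
#' @param tr Repetition time in ms.
#' @param n_averages Number of signal averages (>= 1).
#' @param delta_pairs Optional list of `c(delta, Delta)` gradient timings
#'   (ms), one per TE. Metadata only.
#'
#' @return An object of class `ivim_protocol`.
#' @export
#' @examples
#' p <- default_protocol()
#' p$b_values
acquisition_protocol <- function(b_values, te_values, tr = 2000,
                                 n_averages = 4, delta_pairs = NULL) {
  b_values <- as.numeric(b_values)
  te_values <- as.numeric(te_values)
  if (length(b_values) < 2 || any(b_values < 0) || b_values[1] != 0 ||
      any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing, non-negative and contain 0")
  if (length(te_values) < 1 || any(te_values <= 0) ||
      (length(te_values) > 1 && any(diff(te_values) <= 0)))
    stop("te_values must be strictly increasing and positive")
  if (n_averages < 1) stop("n_averages must be >= 1")
  if (!is.null(delta_pairs) && length(delta_pairs) != length(te_values))
    stop("delta_pairs must have one (delta, Delta) entry per TE")
  structure(list(b_values = b_values, te_values = te_values, tr = tr,
                 n_averages = as.integer(n_averages),
                 delta_pairs = delta_pairs),
            class = "ivim_protocol")
}

#' Study-default acquisition protocol
#'
#' Nine b-values (0, 10, 20, 50, 100, 200, 500, 800, 1000 s/mm^2), echo
#' times 60, 70, 80, 90, 100 and 120 ms, TR 2000 ms and 4 averages — the
#' protocol of the multi-TE prostate study this package reproduces.
#'
#' @return An `ivim_protocol` object.
#' @export
default_protocol <- function() {
  acquisition_protocol(
    b_values = c(0, 10, 20, 50, 100, 200, 500, 800, 1000),
    te_values = c(60, 70, 80, 90, 100, 120),
    tr = 2000, n_averages = 4,
    delta_pairs = list(c(13.9, 29.1), c(18.9, 34.1), c(23.9, 39.1),
                       c(28.9, 44.1), c(33.9, 49.1), c(43.9, 59.1)))
}

#' Ground-truth tissue parameters for one ROI
#'
#' The generating parameters of the two-compartment IVIM model with
#' compartment-specific transverse relaxation. Diffusivities are in mm^2/s
#' (so a typical prostate D is ~1.5e-3); relaxation times in ms. `f` is the
#' T2-free perfusion fraction, i.e. the capillary signal fraction that would
#' be observed at TE = 0.
#'
#' @param s0 Unattenuated signal at TE = 0, b = 0 (> 0, arbitrary units).
#' @param d Tissue diffusion coefficient D in mm^2/s (> 0).
#' @param d_star Pseudo-diffusion coefficient D* in mm^2/s (> d).
#' @param f Perfusion fraction in `[0, 1)`.
#' @param t2_tissue Tissue T2 in ms (> 0).
#' @param t2_blood Blood T2 in ms (> 0).
#'
#' @return An object of class `ivim_ground_truth`.
#' @export
#' @examples
#' gt <- tissue_ground_truth(d = 1.568e-3, d_star = 9.150e-3, f = 0.097)
#' ivim_signal(gt, b = c(0, 200, 1000))
tissue_ground_truth <- function(s0 = 1, d, d_star, f,
                                t2_tissue = 136, t2_blood = 275) {
  if (s0 <= 0) stop("s0 must be positive")
  if (d <= 0) stop("d must be positive")
  if (d_star <= d) stop("d_star must exceed d (pseudo-diffusion is faster)")
  if (f < 0 || f >= 1) stop("f must lie in [0, 1)")
  if (t2_tissue <= 0 || t2_blood <= 0) stop("T2 values must be positive")
  structure(list(s0 = s0, d = d, d_star = d_star, f = f,
                 t2_tissue = t2_tissue, t2_blood = t2_blood),
            class = "ivim_ground_truth")
}

#' Mono-exponential diffusion signal
#'
#' `S(b) = s0 * exp(-b * coef)`, the single-compartment decay used for the
#' apparent diffusion coefficient. `coef` is in mm^2/s and b in s/mm^2.
#'
#' @param s0 Signal at b = 0 (> 0).
#' @param coef Decay coefficient in mm^2/s (>= 0).
#' @param b b-value(s) in s/mm^2 (>= 0); vectorised.
#' @return Signal value(s).
#' @export
monoexp_signal <- function(s0, coef, b) {
  if (s0 <= 0) stop("s0 must be positive")
  if (coef < 0) stop("coef must be non-negative")
  if (any(b < 0)) stop("b must be non-negative")
  s0 * exp(-b * coef)
}

#' Two-compartment IVIM signal
#'
#' `S(b) = s0 * (f * exp(-b * D*) + (1 - f) * exp(-b * D))`: the standard
#' bi-exponential decay of a voxel containing pseudo-diffusing capillary
#' blood (fraction `f`, decay D*) and diffusing tissue water. With
#' `convention = "sum"` the perfusion compartment decays as
#' `exp(-b * (D + D*))` instead; the standalone-D* convention is the
#' default and matches the segmented fitting equations.
#'
#' @param gt An [tissue_ground_truth()] object.
#' @param b b-value(s) in s/mm^2 (>= 0); vectorised.
#' @param convention `"standalone"` (default) or `"sum"`.
#' @return Signal value(s).
#' @export
ivim_signal <- function(gt, b, convention = c("standalone", "sum")) {
  stopifnot(inherits(gt, "ivim_ground_truth"))
  convention <- match.arg(convention)
  if (any(b < 0)) stop("b must be non-negative")
  dperf <- if (convention == "sum") gt$d + gt$d_star else gt$d_star
  gt$s0 * (gt$f * exp(-b * dperf) + (1 - gt$f) * exp(-b * gt$d))
}

#' TE-extended two-compartment IVIM signal
#'
#' Adds compartment-specific T2 decay to the IVIM model:
#' \deqn{S(b, TE) = s0 [ f e^{-TE/T2_b} e^{-b D^*} +
#'                       (1 - f) e^{-TE/T2_t} e^{-b D} ].}
#' Because blood T2 (~275 ms) exceeds prostate tissue T2 (80–136 ms), a
#' longer TE attenuates the tissue compartment more, so at fixed TE the
#' curve is a standard IVIM curve whose perfusion fraction is the inflated
#' [apparent_f()] rather than the true `f`.
#'
#' @inheritParams ivim_signal
#' @param te Echo time in ms (> 0); scalar.
#' @return Signal value(s).
#' @export
extended_ivim_signal <- function(gt, b, te,
                                 convention = c("standalone", "sum")) {
  stopifnot(inherits(gt, "ivim_ground_truth"))
  convention <- match.arg(convention)
  if (length(te) != 1 || te <= 0) stop("te must be a positive scalar")
  if (any(b < 0)) stop("b must be non-negative")
  dperf <- if (convention == "sum") gt$d + gt$d_star else gt$d_star
  gt$s0 * (gt$f * exp(-te / gt$t2_blood) * exp(-b * dperf) +
           (1 - gt$f) * exp(-te / gt$t2_tissue) * exp(-b * gt$d))
}

#' Apparent perfusion fraction at a given echo time
#'
#' Closed-form TE-weighted perfusion fraction of the extended model:
#' \deqn{f_{app}(TE) = \frac{f e^{-TE/T2_b}}
#'   {f e^{-TE/T2_b} + (1 - f) e^{-TE/T2_t}}.}
#' Strictly increasing in TE when tissue T2 < blood T2; identically `f`
#' when the two T2s are equal. This is the quantity a standard (T2-blind)
#' IVIM analysis estimates instead of `f`.
#'
#' @inheritParams extended_ivim_signal
#' @param te Echo time(s) in ms (> 0); vectorised.
#' @return Apparent fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' gt <- tissue_ground_truth(d = 1.2e-3, d_star = 13e-3, f = 0.1,
#'                           t2_tissue = 80, t2_blood = 275)
#' apparent_f(gt, te = c(60, 90, 120))
apparent_f <- function(gt, te) {
  stopifnot(inherits(gt, "ivim_ground_truth"))
  if (any(te <= 0)) stop("te must be positive")
  num <- gt$f * exp(-te / gt$t2_blood)
  den <- num + (1 - gt$f) * exp(-te / gt$t2_tissue)
  ifelse(den == 0, 1, num / den)
}

#' @export
print.ivim_ground_truth <- function(x, ...) {
  cat(sprintf(
    "IVIM ground truth: D = %.3f, D* = %.3f (1e-3 mm^2/s), f = %.3f\n",
    1e3 * x$d, 1e3 * x$d_star, x$f))
  cat(sprintf("  T2 tissue/blood = %.0f/%.0f ms, s0 = %.3g\n",
              x$t2_tissue, x$t2_blood, x$s0))
  invisible(x)
}

#' @export
print.ivim_protocol <- function(x, ...) {
  cat("Acquisition protocol:\n")
  cat("  b-values (s/mm^2):", paste(x$b_values, collapse = ", "), "\n")
  cat("  TE (ms):", paste(x$te_values, collapse = ", "),
      sprintf(" TR = %g ms, averages = %d\n", x$tr, x$n_averages))
  invisible(x)
}
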