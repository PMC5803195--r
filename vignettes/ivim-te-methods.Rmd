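---
title: "Echo-time effects on IVIM quantification: models, fitting and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Echo-time effects on IVIM quantification: models, fitting and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimte)
```

## The problem

Intravoxel incoherent motion (IVIM) imaging decomposes the
diffusion-weighted MR signal of a voxel into a tissue-water compartment
(diffusion coefficient $D$) and a capillary-blood compartment whose
incoherent microcirculation mimics a very fast pseudo-diffusion $D^*$:

$$S(b) = S_0\left[f\,e^{-b D^*} + (1-f)\,e^{-b D}\right],$$

with $f$ the perfusion (signal) fraction at $b = 0$. The standard model
tacitly assumes both compartments share one transverse relaxation time.
They do not: blood $T_2$ (about 275 ms) is far longer than prostate
tissue $T_2$ (about 80 ms in the central zone, CZ, and about 136 ms in
the peripheral zone, PZ). Acquiring at echo time $TE$ therefore weights
the compartments differently,

$$S(b, TE) = S_0\left[f\,e^{-TE/T_{2,b}}e^{-b D^*} +
  (1-f)\,e^{-TE/T_{2,t}}e^{-b D}\right],$$

and a $T_2$-blind analysis at echo time $TE$ does not estimate $f$ but
the *apparent* fraction

$$f_{app}(TE) = \frac{f\,e^{-TE/T_{2,b}}}
  {f\,e^{-TE/T_{2,b}} + (1-f)\,e^{-TE/T_{2,t}}},$$

which grows with $TE$ whenever $T_{2,t} < T_{2,b}$ — strongly in the
short-$T_2$ CZ, weakly in the PZ whose $T_2$ is closer to blood. This
package implements the forward models, the conventional segmented fit,
a joint multi-TE fit that removes the bias, a synthetic cohort generator
shaped like a duplicate-examination multi-TE volunteer study, and the
repeatability statistics used to quantify test-retest precision.

## The segmented fit and its threshold bias

`segmented_fit()` is the classical two-stage estimator:

1. a mono-exponential fit on $b \ge b_{thr}$ (default 200 s/mm²)
   yields $D$ and the extrapolated intercept $S_0'$;
2. $f = 1 - S_0'/S_0$, with $S_0$ the measured $b=0$ signal;
3. with $D$, $f$, $S_0$ fixed, $D^*$ is found by bounded 1-D least
   squares on $b \le b_{thr}$;
4. the ADC is a mono-exponential fit over all b-values.

Mono-exponential fits use nonlinear least squares on the exponential
form (Levenberg–Marquardt via minpack.lm), initialised at the log-linear
OLS solution: the log transform alone would re-weight the noise, and the
deterministic initialisation makes every fit bit-reproducible without a
seed. The $D^*$ stage is a one-parameter bounded problem and is solved
by `stats::optimize` on $[D, 0.5]$ mm²/s to a $10^{-12}$ interval
tolerance; boundary solutions are flagged, and a negative intercept
fraction is clamped to 0 with a flag rather than raised as an error,
mirroring what noisy in-vivo data produce.

Step 1 is exact only if the perfusion signal is fully suppressed above
the threshold. At prostate-typical $D^*$ it is not:
$e^{-200 \cdot 0.00915} \approx 0.16$, so on *noise-free*
bi-exponential curves the intercept $S_0'$ is inflated and the
segmented $f$ is biased low by roughly 10–30% relative (and $D$ high by
1–2.5%), the more so the smaller $b_{thr} D^*$. We verified this against
dense brute-force grid minimisation of the same objectives: the fits
attain the global optimum of the *segmented* objective; the residual
error is intrinsic to the method, not to the optimiser. The package
deliberately does not append an extra joint-refinement stage: the
single-pass algorithm is the method under study. The bias is common to
both examinations of a test-retest pair, so it largely cancels in CV and
Bland-Altman statistics, and it leaves the TE trends qualitatively
intact (the per-TE segmented $f$ still rises with TE exactly when
$T_{2,t} < T_{2,b}$, tracking $f_{app}$ with an offset). The
200 vs 500 s/mm² threshold comparison is exposed via the `b_threshold`
argument. The perfusion compartment decays as $e^{-bD^*}$ by default;
the $e^{-b(D+D^*)}$ convention is available as `convention = "sum"`.

## The TE-corrected fit

`corrected_fit()` jointly fits $(S_0, D, D^*, f, T_{2,t})$ to all
$(b, TE)$ samples of one ROI/exam under the extended model, with blood
$T_2$ fixed (default 275 ms): with only a handful of echo times,
$T_{2,b}$ is not identifiable alongside $T_{2,t}$ and $f$, and blood
$T_2$ is well characterised in the literature. Initialisation comes
from per-TE segmented fits plus a log-linear regression of the $b=0$
signals on TE; bounds keep all parameters physical. At least three
distinct echo times are required. On noise-free extended-model data the
fit recovers $f$, $D$ and $T_{2,t}$ to machine precision, for any TE
subset — the estimated $f$ is TE-free by construction, which is the
sense in which the correction "removes" the TE bias.

## What the synthetic cohort emulates

`generate_dataset()` builds the full factorial design of the emulated
study: 17 subjects × 2 zones × 2 examinations × 6 echo times
(60–120 ms) × 9 b-values (0–1000 s/mm²), with 4 signal averages and a
muscle noise-reference region per examination and TE. Choices, made
once:

* **Zone parameter distributions.** Truncated normals per subject and
  zone, centred on published normal-prostate values (PZ: $D$ 1.568 ±
  0.187, $D^*$ 9.150 ± 1.634 (10⁻³ mm²/s), $f$ 0.097 ± 0.031; CZ: $D$
  1.211 ± 0.125, $D^*$ 13.443 ± 3.411, $f$ 0.111 ± 0.032). Truncation
  bounds are physiological ($f \in [0.02, 0.4]$, $D^* \ge 1.5 D$,
  $T_{2,t} \in [20, 400]$ ms): healthy prostate does not plausibly
  contain near-zero-perfusion ROIs, and allowing them would make the
  intercept fraction degenerate under noise.
* **Tissue T2 spread.** Mean 136 ms (PZ) / 80 ms (CZ), blood fixed at
  275 ms. The literature "±" on these $T_2$ values mixes
  between-study and measurement variance; adopting it wholesale as
  between-subject variance would inflate the cross-sectional spread of
  the apparent $f$ far beyond the dispersions such studies report, so
  the between-subject SD is set to 15 ms.
* **Noise.** Rician on magnitudes — each acquisition is
  $\sqrt{(S+g_1)^2 + g_2^2}$ with Gaussian channel noise — averaged
  arithmetically over the 4 acquisitions; the in-scanner geometric
  averaging over diffusion directions is absorbed into the magnitude
  model (directions are not simulated). A `sigma = 0` setting gives the
  noise-free limit in which both examinations coincide.
* **SNR calibration.** Each ROI's $S_0$ is scaled so its noise-free
  SNR at $b = 1000$ s/mm² and the shortest TE — defined operationally
  as ROI signal over the SD of the muscle reference on the averaged
  image — hits the midpoint of the target band [18, 21]. SNR then
  decays with TE through the $T_2$ weights, which is the qualitative
  behaviour such protocols show. The muscle reference is a constant
  baseline plus the same noise process; 1000 reference pixels (bilateral
  ellipses pooled over slices) keep the SD estimate, whose relative
  error is $1/\sqrt{2(n-1)}$, near 2% so that realised SNR curves are
  reliably monotone.
* **Test-retest structure.** The two examinations are independent noise
  realisations of identical ground truth — repositioning,
  physiological drift and segmentation variability are *not* simulated.
  Simulated CVs therefore isolate the noise-propagation component of
  repeatability; passing tests show the estimator ranking
  (ADC ≈ D more repeatable than f, in turn more repeatable than D*),
  not the absolute in-vivo CV magnitudes.

All randomness flows from one seed; regenerating with the same
configuration is byte-identical.

## Repeatability statistics

`cv_test_retest()` uses the root-mean-square within-subject CV,
$100\sqrt{\mathrm{mean}_i\,(x_{i1}-x_{i2})^2/2}\,/\,\bar x$ — the
standard estimator for paired test-retest data; the mean of per-subject
CVs is available as `method = "per_subject"`. Bins: ≤ 10% good, 10–25%
moderate, ≥ 25% poor. `bland_altman_percent()` reports the mean
per-subject percentage difference (denominator: pair mean) with 95%
limits of agreement bias ± 1.96 SD. `spearman_te_trend()` pools
(value, TE) points and uses midrank ties, binning |ρ| at
0.25/0.5/0.75 (left-closed); a constant input yields a flagged
undefined result. `anova_across_te()` is the classical equal-variance
one-way F test. p-values are reported, never used to gate any pipeline
stage, and no multiple-testing correction is applied. In `run_study()`,
pairs containing a failed fit (fraction clamped to zero) are excluded
from CV/Bland-Altman with the retained pair count reported — failed
fits carry no repeatability information, and the clamp counts are part
of the study provenance.

## Numerical and design notes

* Internally b is in s/mm² and diffusivities in mm²/s; tables report
  diffusivities in the conventional 10⁻³ mm²/s.
* The historical intercept formula "$f = (1 - S_0')/S_0$" is
  dimensionally consistent only for $S_0$-normalised signals; the
  package uses the equivalent normalised form $f = 1 - S_0'/S_0$.
* "Fit over 0–200 s/mm²" for $D^*$ is read as the restricted subset
  with $D$, $f$, $S_0$ held fixed; fitting $D^*$ against all b-values
  instead is exposed as `dstar_subset = "all"`.
* TR/T1 saturation is not modelled (TR was fixed in the emulated
  protocol and no $T_1$ values are available); gradient timings are
  carried as protocol metadata only. One-way (not repeated-measures)
  ANOVA is used across TE levels.
* Convergence: Levenberg–Marquardt runs with `ftol`/`ptol` near machine
  precision and up to 1000 iterations; all fits are deterministic.

## Problem sizes used by the test-suite

The bundled checks run a full default cohort (3 672 signal values,
408 segmented fits, about 1.5 s), 20 single-TE replicate studies for the
CV ranking, 10 full replicate studies for the TE-trend comparison,
200-replicate noise simulations for error-spread ordering, and 10⁴
null simulations for ANOVA type-I calibration — sizes chosen so each
property is measured with comfortable statistical margin while the whole
suite stays interactive.

## Worked example

```{r example, eval = FALSE}
study <- run_study(cohort_config(seed = 1))
subset(study$repro_table, te_ms == 60)
subset(study$trend_table, parameter == "f")
```

## Known limitations

* The segmented estimates carry the threshold bias described above on
  truly bi-exponential signals; comparisons across sites should use one
  fixed threshold and TE.
* Blood $T_2$ must be supplied, not estimated; an inaccurate fixed value
  biases the corrected $f$ proportionally.
* The generator does not simulate repositioning, motion,
  direction-dependent diffusion, partial volume or $T_1$ effects, so
  absolute simulated CVs are optimistic relative to in-vivo values.
* NIfTI ingestion reduces voxels to ROI means; voxelwise parameter maps
  are out of scope for the statistics.
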