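---
title: "Models and methods behind fusmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fusmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fusmap` implements the analysis chain of an awake-primate functional
ultrasound (fUS) visual-mapping experiment together with a synthetic
generator of such data. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic
validation does and does not establish.

## The measurement model

fUS estimates cerebral blood volume (CBV) from the power of the blood
echo after tissue clutter is removed. The package models one
acquisition block as a complex space-by-time Casorati matrix

$$ C = T + B, $$

where the tissue component $T$ is low-rank (rank $\le 3$ here: strong,
spatially coherent, slowly drifting) and the blood component $B$ is a
sum of independent moving scatterers whose per-frame phase advance is
the Doppler shift $f_D = 2 v f_0 / c$ ($f_0$ = 15 MHz, $c$ = 1540 m/s;
1 mm/s of axial speed is ~19.5 Hz, well resolved at the 500-Hz frame
rate). Clutter filtering truncates the leading singular components of
$C$; the power-Doppler value of a pixel is then the mean squared
magnitude over the block's 200 frames, which for independent scatterer
phases has expectation equal to the local scatterer count — the basis
for treating power Doppler as proportional to CBV.

Assumptions worth stating: the tissue subspace must not overlap the
blood subspace (true by construction in the generator; approximately
true in vivo when tissue motion is slow and coherent), and the number
of removed components must be at least the tissue rank. The cut
`n_cut` is a free parameter; a fixed cut keeps runs deterministic, and
an optional elbow rule (maximum curvature of the log singular-value
curve) is provided for exploration. The retained subspace corresponds
physically to blood speeds of roughly 1–25 mm/s; the package documents
this meaning but deliberately implements no extra frequency band-pass,
because the filtering step is defined purely by the SVD truncation.

## The hemodynamic and tuning model of the generator

Pixel time courses at 1 Hz are

$$ S_p(t) = B_p\Big(1 + \sum_i a\, w_{p,c(i)}\, k(t - t_i)\Big) +
   \varepsilon_p(t), $$

with baseline $B_p$, trial onsets $t_i$, response amplitude $a$
(percent of baseline; default 20%, within the 10–40% range typical of
these recordings), and a unimodal causal kernel $k$ from the gamma
family, parameterised by its peak delay (default 2.5 s, the observed
CBV peak latency for brief visual stimuli) and FWHM (default 2 s —
chosen so the kernel is comfortably resolved by the 1-s averaging
windows used downstream and has decayed below 5% of its peak by 10 s).
The shape/scale pair is solved numerically from these two constraints
at model construction.

The weight $w$ encodes functional preference. For retinotopic
protocols it is a Gaussian in the distance between the condition value
and the pixel's preferred eccentricity (SD 1.5 DVA, one condition
step) or polar angle (SD 15°, one wedge). For ocular-dominance trials
it is an eye-gated laminar modulation
$w = \tfrac12\,(1 + g_{\ell}\, \phi_p\, e)$, with $\phi_p = \pm 1$ the
square-wave column phase along the ribbon's arc length (sign change
every `od_column_width` µm, so one full left+right period spans two
band widths), $e = \pm 1$ the stimulated eye, and $g_\ell$ a per-layer
modulation depth (defaults: IV = 1, II/III = V = 0.5, I = VI = 0.1,
mirroring the laminar profile of thalamic input). Columns have sharp
borders and multiplicative modulation — the simplest model producing
the alternating-band structure the analysis targets.

Noise is additive Gaussian on Doppler intensity, i.i.d. per
pixel-frame, with SD expressed in percent of the local baseline
(default 15%, which makes single-trial activation maps visibly
unreliable and 10–20-trial averages clean, the regime the reliability
analysis probes). The real per-pixel noise distribution of such
recordings is not characterised in detail; this default is a stated
assumption, not a measured fact.

The geometry is a ribbon of configurable thickness (default 1.6 mm)
around a polyline midline in the 98 × 128-pixel plane (0.11 mm lateral
× 0.1 mm depth pitch, 14 × 10 mm field). The default midline carries a
single smooth fold; no attempt is made to reproduce real anatomy.
Depth fractions are indexed into layers I, II/III, IV, V, VI with a
configurable Hässler-style fraction table (defaults 0–0.08, 0.08–0.35,
0.35–0.60, 0.60–0.80, 0.80–1.0); published laminar schemes give no
canonical numeric boundaries, so these are package conventions.

## Preprocessing choices

The fixed order is upsample → smooth → epoch → normalize.

* Temporal upsampling: cubic splines (`stats::spline`, `fmm`), factor
  10 (1 Hz → 0.1 s). Spline interpolation is linear in the data, so it
  is applied as a precomputed operator matrix; knot values are
  preserved exactly and cubic signals are reproduced to machine
  precision away from the boundary.
* Spatial-temporal smoothing: the "3×3×3, SD 0.65" smoothing of the
  original description is contradictory as written (a box kernel has
  no SD); it is implemented as a normalized 3×3×3 truncated Gaussian
  with σ = 0.65 voxels — the common smooth-3D idiom that description
  mirrors. The kernel is separable and applied with nearest-value edge
  padding so the cortical surface rows do not ring. Its sum of squared
  weights (≈ 0.095) is the analytic white-noise variance-shrinkage
  factor the tests verify.
* Epochs span −5…+10 s around correct-trial onsets (5-s baseline, the
  longest response window, and the return to baseline); trials whose
  epoch does not fit in the session are dropped with a warning, never
  motion-corrected. ΔCBV is percent change over the 5-s pre-onset
  baseline mean, which makes the baseline-window mean of every
  normalized trial identically zero (a tested invariant).

## Analysis choices

**Reliability.** Sessions need 40 trials of a condition (20 for the
reference map + the combination pool); longer sessions are split into
notional 40-trial sessions. Combinations are drawn without replacement
within a draw, 100 draws per n, seeded. Proportions are averaged
combinations → session → grand mean. The Naka–Rushton fit
$p(n) = b + r_\max n^e/(n^e + n_{50}^e)$ profiles $b$ and $r_\max$
exactly (they are linear given the shape), grids over $(n_{50}, e)$,
and polishes with Nelder–Mead — deterministic, no random starts. The
map SNR is defined as $10\log_{10}$(mean active-ROI response / SD of
quiet-ROI values); the source experiments report dB values without a
formula, so this definition is the package's convention.

**Retinotopy.** Tuning is fitted over condition *values* (DVA or
degrees), not indices, so the ±2-DVA repeatability tolerance is
meaningful; the polar-angle protocol lives on a linear 0–180° domain
(one hemifield), so no circular statistics are needed. The grid over
(center, width) with exact linear amplitude/offset makes the per-pixel
fit deterministic and fast; `fit_pixel_tuning()` adds a Nelder–Mead
polish for single-pixel use. Validity combines the R² > 0.02 threshold
with a positive amplitude and a center strictly inside the stimulated
range. One caveat is documented deliberately: with 9–12 samples and a
flexible best-of-grid fit, iid noise alone produces R² well above 0.02
at a large fraction of pixels, so the R² threshold separates signal
from noise scenes only partially; the tests therefore check the
contrast between signal and noise scenes rather than an absolute
noise-validity rate. Post-filter sizes (3×3 median, nearest-valid hole
filling, lateral 1×3 mean) are conventions chosen to be the smallest
neighbourhoods implementing the named filters; all are order
statistics or convex averages, so they cannot move a center outside
the stimulated range. The width map stores the Gaussian SD; FWHM is
SD × 2.355 if needed.

**Ocular dominance.** Maps are standardized (z-scored) over the crop
region before subtraction — the crop, not the full image, because the
analysis region is what the operator crops to. Laminar profiles are
centered, resampled at 100 µm (about one pixel; profiles under 10
samples are rejected), and fitted with `stats::smooth.spline`, with
smoothing chosen by generalized cross-validation unless a fixed `spar`
is supplied. Peak finding runs on the spline fit (prominence ≥ 0.75,
|value| > 0.25, MATLAB-style topographic prominence); spectra are
computed on the *resampled raw* profile (unpadded FFT, one-sided,
3-sample moving average, max-normalized) so that the spectral index
retains its flat-spectrum baseline of band-width/Nyquist ≈ 0.14 under
pure noise. The zero-frequency bin is included in the index
denominator, which is what lets a structure-free region score low. The
even/odd shuffle control pools both eyes in time order, averages even
and odd positions separately, and sends the pair through the same
standardize-and-subtract path; a consistent eye-specific signal
cancels exactly, and with an odd trial count the halves differ by one
trial rather than discarding any.

## Problem sizes and determinism

The test-suite and acceptance runs use sessions of 8–44 trials on the
full 98 × 128 plane (or a 30 × 80 straight-ribbon scene for fast unit
tests), 10–50 Monte-Carlo frame blocks of 10–16 pixels square, and 20
paired seeds for the shuffle null — sizes at which every check runs in
seconds to a couple of minutes while leaving Monte-Carlo tolerances
comfortable. In the noiseless reliability check the intertrial
interval is raised to 12 s so the hemodynamic tail of one trial cannot
leak into the next epoch's baseline: with overlapping tails, otherwise
identical trials differ minutely and near-threshold pixels flip, which
is a property of the protocol, not of the estimator. All stochastic
stages take explicit integer seeds and are bit-reproducible; the
pipeline runner records a configuration hash in every report.

## Limitations

The generator emulates the statistical structure the analysis assumes
— low-rank clutter, Poisson scatterers, Gaussian pixel noise, sharp
square-wave columns, exact Gaussian tuning — not the physics of
beamforming, speckle, eye movements, or real cortical anatomy. Passing
recovery tests therefore demonstrates that the estimators are correct
and unbiased under their own model, including at realistic noise
levels, but not that real tissue satisfies that model: real data add
motion artifacts, spatially correlated and non-Gaussian noise, drifts,
and anatomical irregularity that only scanner recordings can probe.
Classification percentages, SNRs and repeatability values measured on
synthetic sessions are internally consistent quantities, not
predictions of the values measurable in any particular animal.
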