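# fusmap

Functional ultrasound (fUS) imaging measures cerebral blood volume (CBV)
at mesoscopic resolution by forming ultrasensitive power-Doppler images
from ultrafast plane-wave acquisitions. In the awake primate visual
cortex this is enough to resolve retinotopic gradients and, at
~100-µm pixel pitch, the columnar ocular-dominance (OD) bands of V1.
`fusmap` implements the complete analysis chain for such experiments —
and a ground-truth synthetic-data generator emulating them — so that
every stage can be developed, tested and validated without scanner
data. It is aimed at neuroimaging methodologists and fUS practitioners
who need a reproducible, scriptable reference pipeline.

## What it computes

**Doppler formation.** Each 0.4-s block of 200 compounded frames
(15 plane waves, PRF 7,500 Hz, frame rate 7,500/15 = 500 Hz) is
reshaped into a Casorati matrix **C** (space × time) and clutter-filtered
by truncating its leading singular components,

> C_f = C − Σ_{i≤k} σᵢ uᵢ vᵢᴴ,

after which the power-Doppler image is the per-pixel mean squared
magnitude over frames — proportional to the number of moving blood
scatterers. One image per second; a 60-minute session yields 3,600
images of 98 × 128 pixels (0.11 × 0.1 mm pitch).

**CBV preprocessing.** 1-Hz series are cubic-spline upsampled 10× to
0.1 s, smoothed with a 3×3×3 Gaussian-weighted kernel (SD 0.65 voxels),
epoched around each correct-trial onset, and converted to percent
change over the 5-s pre-onset baseline:
ΔCBV(t) = 100 · (S(t) − S̄_base)/S̄_base.

**Activation & reliability.** Maps are windowed response means
(2–3 s post onset; 2.5–3 s for retinotopy; 2.5–3.5 s for OD),
binarized at +10% ΔCBV. Reliability versus trial count is the fraction
of pixels classified identically to a 20-trial reference map, averaged
over 100 random trial combinations per n = 1…20, and fitted with a
Naka–Rushton function p(n) = b + r_max·nᵉ/(nᵉ + n₅₀ᵉ).

**Retinotopy.** Per-pixel Gaussian tuning over the 9 eccentricity
(1.5–15 DVA) or 12 polar-angle (15°-wide) conditions; pixels with
R² > 0.02 form the preference map, post-filtered by a 3×3 median,
nearest-valid hole filling, and a lateral 1×3 mean.

**Ocular dominance.** OD index = standardized contralateral map −
standardized ipsilateral map. Laminar profiles (Hässler-scheme layer
segmentation between operator-supplied cortical boundary paths) are
spline-fitted; extrema with prominence ≥ 0.75 and |value| > 0.25 give
the mean bandwidth (pooled half-distances between consecutive maxima /
minima). The spatial-frequency spectrum of each layer profile (FFT,
3-sample moving average, max-normalized) is summarized by the spectral
index: the fraction of the spectrum within 1/(2·700)–1/(2·350) µm⁻¹,
the band of classical 350–700-µm OD bands. An even/odd trial shuffle
provides the null control.

## Worked example

Ocular-dominance quantification on a synthetic scene with 520-µm
columns (SNR 5, 10 trials per eye):

```r
library(fusmap)

cortex <- make_cortex(od_column_width = 520)
events <- make_event_log(stimulus_set("od"), n_trials_per_condition = 10,
                         seed = 1)
series <- simulate_cbv_series(cortex, events, noise_sd = 4, seed = 1)
tensor <- preprocess_series(series, events)
od     <- od_map_from_tensor(tensor, crop = cortex$mask)

profile <- layer_profile(od, cortex, layer = "IV")
bw <- mean_bandwidth(find_extrema(profile))
sprintf("OD bandwidth: %.1f um (SEM %.1f, %d intervals)",
        bw$mean_um, bw$sem_um, bw$n_intervals)
#> "OD bandwidth: 521.2 um (SEM 7.9, 26 intervals)"

layer_selectivity_table(od, cortex)
#> # A tibble: 5 × 3
#>   roi   layer  spectral_index
#>   <chr> <chr>           <dbl>
#> 1 all   I               0.408
#> 2 all   II/III          0.526
#> 3 all   IV              0.572
#> 4 all   V               0.523
#> 5 all   VI              0.381
```

The recovered bandwidth matches the generated 520-µm columns to a
fraction of a pixel, and the spectral index peaks in layer IV, where
the generator places the strongest OD modulation (layers II/III and V
at half strength). `autoplot()` methods display every result type
(activation, preference and OD maps, reliability curves, laminar
profiles, spectra); `tidy()`/`glance()` summarize the Naka–Rushton and
tuning fits.

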