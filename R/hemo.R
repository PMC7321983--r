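#' Hemodynamic response model
#'
#' A unimodal, causal gamma-family kernel parameterised by its peak delay
#' and full width at half maximum (FWHM). The kernel is normalised to a
#' peak of 1 so that the per-trial percent-CBV response amplitude is read
#' directly off `response_amplitude`. With the defaults (peak 2.5 s,
#' FWHM 2 s) the kernel has returned below 5% of its peak by 10 s, which
#' keeps a 15-s epoch self-contained.
#'
#' @param peak_delay Seconds from stimulus onset to the CBV peak.
#' @param fwhm Kernel full width at half maximum (s).
#' @param response_amplitude Peak percent-CBV response of a perfectly
#'   matched pixel to one trial (the generator draws no variability on
#'   this; tuning and OD gating scale it down).
#' @param tuning_width_ecc Gaussian tuning SD in DVA.
#' @param tuning_width_ang Gaussian tuning SD in degrees.
#' @return Object of class `fus_hemo` with the gamma shape/scale solved
#'   numerically from (`peak_delay`, `fwhm`).
#' @export
hemodynamic_model <- function(peak_delay = 2.5, fwhm = 2,
                              response_amplitude = 20,
                              tuning_width_ecc = 1.5,
                              tuning_width_ang = 15) {
  stopifnot(peak_delay > 0, fwhm > 0)
  kern_fwhm <- function(shape) {
    theta <- peak_delay / (shape - 1)
    lf <- function(t) (shape - 1) * log(t / peak_delay) -
      (t - peak_delay) / theta          # log kernel, peak log = 0
    lo <- stats::uniroot(function(t) lf(t) - log(0.5),
                         c(peak_delay * 1e-30, peak_delay))$root
    hi <- stats::uniroot(function(t) lf(t) - log(0.5),
                         c(peak_delay, peak_delay * 50))$root
    hi - lo
  }
  shape <- stats::uniroot(function(a) kern_fwhm(a) - fwhm,
                          c(1.05, 500), tol = 1e-10)$root
  structure(list(
    peak_delay = peak_delay, fwhm = fwhm,
    shape = shape, scale = peak_delay / (shape - 1),
    response_amplitude = response_amplitude,
    tuning_width_ecc = tuning_width_ecc,
    tuning_width_ang = tuning_width_ang
  ), class = "fus_hemo")
}

#' Evaluate the hemodynamic kernel
#'
#' @param hemo A [hemodynamic_model()].
#' @param t Times in seconds relative to stimulus onset (vectorised).
#' @return Kernel values; 0 for `t <= 0`, peak 1 at `peak_delay`.
#' @export
hemo_kernel <- function(hemo, t) {
  k <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  k[pos] <- exp((hemo$shape - 1) * log(tp / hemo$peak_delay) -
                  (tp - hemo$peak_delay) / hemo$scale)
  k
}
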