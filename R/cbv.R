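#' Preprocessing parameters
#'
#' Bundles the fixed preprocessing settings: 10x cubic-spline temporal
#' upsampling (1 Hz to 0.1 s), 3x3x3 Gaussian-weighted smoothing with
#' SD 0.65 voxels, a 5-s pre-onset baseline, and the per-protocol
#' response-averaging windows (seconds post onset): reliability analysis
#' 2--3 s, retinotopy 2.5--3 s, ocular dominance 2.5--3.5 s.
#'
#' @param interp_factor Temporal upsampling factor (>= 1).
#' @param smooth_sd Smoothing kernel SD in voxels.
#' @param baseline_s Baseline window length before onset (s).
#' @param windows Named list of `c(start, end)` response windows (s).
#' @param epoch Epoch span around onset, `c(start, end)` in s.
#' @return List of class `fus_preproc_params`.
#' @export
preproc_params <- function(interp_factor = 10,
                           smooth_sd = 0.65,
                           baseline_s = 5,
                           windows = list(fig1 = c(2, 3),
                                          retinotopy = c(2.5, 3),
                                          od = c(2.5, 3.5)),
                           epoch = c(-5, 10)) {
  stopifnot(interp_factor >= 1, baseline_s > 0, epoch[1] <= -baseline_s)
  for (w in windows) stopifnot(w[1] < w[2], w[1] >= epoch[1], w[2] <= epoch[2])
  structure(list(interp_factor = interp_factor, smooth_sd = smooth_sd,
                 baseline_s = baseline_s, windows = windows,
                 epoch = epoch),
            class = "fus_preproc_params")
}

#' Cubic-spline temporal upsampling
#'
#' Interpolates each pixel's time course with a cubic spline evaluated
#' at `factor` times the original sampling rate. Values at the original
#' knots are preserved exactly, and cubic polynomials are reproduced to
#' machine precision away from the boundary.
#'
#' @param series A `fus_series`.
#' @param factor Upsampling factor (10 gives 0.1-s resolution from 1 Hz).
#' @return A `fus_series` with `dt = dt / factor`.
#' @export
interpolate_temporal <- function(series, factor = 10) {
  d <- dim(series$images)
  if (d[3] < 4) stop("need at least 4 frames for cubic-spline upsampling")
  if (factor == 1) return(series)
  x <- seq_len(d[3])
  xout <- seq(1, d[3], by = 1 / factor)
  # spline interpolation is linear in the data: build the operator once
  # by interpolating unit impulses, then apply to all pixels via BLAS
  W <- vapply(seq_len(d[3]), function(j) {
    e <- numeric(d[3]); e[j] <- 1
    stats::spline(x, e, xout = xout, method = "fmm")$y
  }, numeric(length(xout)))
  M <- matrix(series$images, d[1] * d[2], d[3])
  out <- M %*% t(W)
  new_series(array(out, c(d[1], d[2], length(xout))),
             dt = series$dt / factor, t0 = series$t0,
             pitch = series$pitch, meta = series$meta)
}

# Separable 1D pass of the [w1, w0, w1] kernel along one margin of a 3D
# array, with nearest-value (replicate) edge padding.
smooth_axis <- function(arr, axis, w0, w1) {
  n <- dim(arr)[axis]
  if (n < 2) return(arr)
  lo <- c(1, seq_len(n - 1))     # index shifted toward start, replicated
  hi <- c(seq_len(n - 1) + 1, n) # shifted toward end
  idx <- function(i) switch(axis,
                            arr[i, , , drop = FALSE],
                            arr[, i, , drop = FALSE],
                            arr[, , i, drop = FALSE])
  w0 * arr + w1 * (idx(lo) + idx(hi))
}

#' 3D spatiotemporal smoothing
#'
#' Convolves the (z, x, t) data with a normalised 3x3x3
#' Gaussian-weighted kernel of SD `sd` voxels (DC gain exactly 1),
#' applied separably with nearest-value edge padding so the cortical
#' surface rows do not ring.
#'
#' @param series A `fus_series` (normally after [interpolate_temporal()]).
#' @param sd Kernel SD in voxels.
#' @return Smoothed `fus_series`.
#' @export
smooth3d <- function(series, sd = 0.65) {
  w1 <- exp(-1 / (2 * sd^2))
  norm <- 1 + 2 * w1
  w0 <- 1 / norm; w1 <- w1 / norm
  arr <- series$images
  for (ax in 1:3) arr <- smooth_axis(arr, ax, w0, w1)
  out <- series
  out$images <- arr
  out
}

# Sum of squared weights of the separable 3x3x3 kernel: white-noise
# variance shrinks by exactly this factor.
smooth_kernel_ssq <- function(sd = 0.65) {
  w1 <- exp(-1 / (2 * sd^2))
  k <- c(w1, 1, w1) / (1 + 2 * w1)
  sum(k^2)^3
}

#' Epoch and baseline-normalize trials
#'
#' Cuts the preprocessed series into per-trial epochs around each
#' correct-trial stimulus onset and converts to percent CBV change:
#' `100 * (S(t) - S_baseline) / S_baseline`, where the baseline is the
#' per-pixel mean over the 5 s preceding onset. Incorrect trials are
#' excluded; trials whose epoch does not fit in the session are dropped
#' with a warning.
#'
#' @param series A `fus_series`, already interpolated and smoothed.
#' @param events A `fus_event_log`.
#' @param params [preproc_params()].
#' @param pixels Optional integer vector of linear pixel indices to
#'   keep (default: all pixels).
#' @return A `fus_trial_tensor`: `data` array
#'   `[pixels x time x trials]` in percent CBV, `rel_time` (s around
#'   onset), `pixel_index`, image `dim`, and per-trial `condition_id`.
#' @export
epoch_and_normalize <- function(series, events, params = preproc_params(),
                                pixels = NULL) {
  d <- dim(series$images)
  npix_all <- d[1] * d[2]
  pixels <- pixels %||% seq_len(npix_all)
  M <- matrix(series$images, npix_all, d[3])[pixels, , drop = FALSE]
  dt <- series$dt
  rel <- seq(params$epoch[1], params$epoch[2], by = dt)
  base_idx <- which(rel >= -params$baseline_s & rel < 0)
  ev <- events[events$correct, , drop = FALSE]
  keep <- logical(nrow(ev))
  cols <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    j <- round((ev$t_onset[i] + rel - series$t0) / dt) + 1
    if (j[1] >= 1 && j[length(j)] <= d[3]) {
      keep[i] <- TRUE
      cols[[i]] <- j
    }
  }
  if (!all(keep)) {
    warning(sum(!keep), " trial(s) dropped: epoch outside the session")
  }
  ev <- ev[keep, , drop = FALSE]
  cols <- cols[keep]
  arr <- array(NA_real_, c(length(pixels), length(rel), nrow(ev)))
  for (i in seq_along(cols)) {
    Si <- M[, cols[[i]], drop = FALSE]
    b <- rowMeans(Si[, base_idx, drop = FALSE])
    arr[, , i] <- 100 * (Si - b) / b
  }
  structure(list(data = arr, rel_time = rel,
                 pixel_index = pixels, dim = d[1:2],
                 condition_id = ev$condition_id,
                 trial_id = ev$trial_id,
                 t_onset = ev$t_onset,
                 params = params,
                 meta = series$meta),
            class = "fus_trial_tensor")
}

#' @export
print.fus_trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<fus_trial_tensor> ", d[1], " pixels x ", d[2], " samples x ",
      d[3], " trials; epoch ", x$rel_time[1], "..",
      x$rel_time[length(x$rel_time)], " s\n", sep = "")
  invisible(x)
}

#' Windowed response means
#'
#' Mean percent-CBV within a post-onset window, per pixel and trial.
#'
#' @param tensor A `fus_trial_tensor`.
#' @param window `c(start, end)` seconds post onset (inclusive), or the
#'   name of a protocol window in the tensor's parameters
#'   (`"fig1"`, `"retinotopy"`, `"od"`).
#' @return Matrix `pixels x trials` (percent CBV).
#' @export
response_mean <- function(tensor, window = "fig1") {
  if (is.character(window)) window <- tensor$params$windows[[window]]
  stopifnot(window[1] >= tensor$rel_time[1],
            window[2] <= tensor$rel_time[length(tensor$rel_time)])
  sel <- which(tensor$rel_time >= window[1] - 1e-9 &
                 tensor$rel_time <= window[2] + 1e-9)
  out <- apply(tensor$data[, sel, , drop = FALSE], c(1, 3), mean)
  attr(out, "window") <- window
  out
}

#' One-call preprocessing: interpolate, smooth, epoch, normalize
#'
#' Applies the fixed preprocessing order (upsample, 3D smooth, epoch,
#' baseline-normalize) to a Doppler series and event log.
#'
#' @inheritParams epoch_and_normalize
#' @param interp_factor,smooth_sd See [preproc_params()].
#' @return A `fus_trial_tensor`.
#' @export
preprocess_series <- function(series, events, params = preproc_params(),
                              pixels = NULL) {
  series <- interpolate_temporal(series, params$interp_factor)
  series <- smooth3d(series, params$smooth_sd)
  epoch_and_normalize(series, events, params, pixels = pixels)
}
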