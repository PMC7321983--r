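new_series <- function(images, dt = 1, t0 = 0,
                       pitch = c(z = 0.1, x = 0.11, slice = 0.4),
                       meta = list()) {
  stopifnot(length(dim(images)) == 3, all(is.finite(images)))
  structure(list(images = images, dt = dt, t0 = t0,
                 pitch = pitch, meta = meta),
            class = "fus_series")
}

#' @export
print.fus_series <- function(x, ...) {
  d <- dim(x$images)
  cat("<fus_series> ", d[1], "x", d[2], " pixels, ", d[3],
      " frames at ", 1 / x$dt, " Hz (t0 = ", x$t0, " s)\n", sep = "")
  invisible(x)
}

#' Times of the frames in a series
#' @param series A `fus_series`.
#' @return Numeric vector of frame times (s).
#' @export
series_times <- function(series) {
  series$t0 + (seq_len(dim(series$images)[3]) - 1) * series$dt
}

# Per-pixel response weight for every condition: Gaussian tuning in the
# stimulus coordinate, or eye-gated laminar OD modulation.
condition_weights <- function(cortex, stimuli, hemo) {
  mask <- as.vector(cortex$mask)
  n <- sum(mask)
  kind <- attr(stimuli, "kind") %||% stimuli$stimulus_kind[1]
  W <- matrix(0, n, nrow(stimuli))
  if (kind == "eccentricity" || kind == "angular") {
    pref <- as.vector(if (kind == "eccentricity") cortex$ecc_pref
                      else cortex$ang_pref)[mask]
    tw <- if (kind == "eccentricity") hemo$tuning_width_ecc
          else hemo$tuning_width_ang
    for (j in seq_len(nrow(stimuli))) {
      W[, j] <- exp(-(stimuli$value[j] - pref)^2 / (2 * tw^2))
    }
  } else {
    phase <- as.vector(cortex$od_phase)[mask]
    layer <- as.vector(cortex$layer_index)[mask]
    gain <- unname(cortex$od_layer_gain[as.character(layer)])
    gain[is.na(gain)] <- 0
    for (j in seq_len(nrow(stimuli))) {
      eye <- stimuli$value[j] # +1 contra, -1 ipsi
      W[, j] <- 0.5 * (1 + gain * phase * eye)
    }
  }
  W
}

#' Simulate a 1-Hz power-Doppler CBV series
#'
#' Synthesises the per-pixel Doppler time course the downstream analysis
#' assumes: `baseline * (1 + sum of tuned trial responses convolved with
#' the hemodynamic kernel) + noise`. The tuned weight of a trial at a
#' pixel is a Gaussian in the distance between the condition value and
#' the pixel's preference (retinotopic protocols) or an eye-gated,
#' laminar-depth-modulated OD weight (`0.5 * (1 + gain * phase * eye)`).
#' Noise is additive Gaussian on Doppler intensity, i.i.d. per
#' pixel-frame, with SD expressed in percent of the local baseline so
#' that percent-CBV noise is `noise_sd` regardless of baseline level.
#' The full ground truth is retained in `$meta` for recovery tests.
#'
#' @param cortex A [make_cortex()] scene.
#' @param events A [make_event_log()] log (its stimulus set is carried
#'   in the log's attributes unless overridden).
#' @param hemo A [hemodynamic_model()].
#' @param noise_sd Noise SD, percent of baseline (>= 0).
#' @param stimuli Stimulus set; defaults to the one in `events`.
#' @param baseline_in,baseline_out Baseline Doppler intensity inside and
#'   outside the cortical mask (arbitrary units).
#' @param duration Session length in seconds; defaults to the last onset
#'   plus a 10-s tail.
#' @param seed Integer seed.
#' @return A `fus_series` at 1 Hz.
#' @export
simulate_cbv_series <- function(cortex, events,
                                hemo = hemodynamic_model(),
                                noise_sd = 15,
                                stimuli = attr(events, "stimuli"),
                                baseline_in = 100, baseline_out = 30,
                                duration = NULL, seed = 1) {
  if (noise_sd < 0) stop("negative noise_sd")
  if (is.null(stimuli)) stop("no stimulus set supplied or attached")
  need <- max(events$t_onset) + max(events$stim_duration) + 10
  duration <- duration %||% ceiling(need)
  if (duration < need) stop("session too short for all events + 10-s tail")
  withr_seed(seed)

  nz <- cortex$dim[["nz"]]; nx <- cortex$dim[["nx"]]
  npix <- nz * nx
  times <- seq(0, duration, by = 1)
  Tn <- length(times)
  mask <- as.vector(cortex$mask)

  W <- condition_weights(cortex, stimuli, hemo)
  resp <- matrix(0, sum(mask), Tn)
  amp <- hemo$response_amplitude / 100
  for (i in seq_len(nrow(events))) {
    cid <- events$condition_id[i]
    if (cid == 0L) next
    j <- match(cid, stimuli$condition_id)
    k <- hemo_kernel(hemo, times - events$t_onset[i])
    nzk <- which(k > 0)
    if (!length(nzk)) next
    resp[, nzk] <- resp[, nzk] + (amp * W[, j]) %o% k[nzk]
  }

  base <- ifelse(mask, baseline_in, baseline_out)
  S <- matrix(base, npix, Tn)
  S[mask, ] <- S[mask, ] * (1 + resp)
  if (noise_sd > 0) {
    S <- S + (noise_sd / 100) * base *
      matrix(stats::rnorm(npix * Tn), npix, Tn)
  }
  new_series(array(S, c(nz, nx, Tn)), dt = 1, t0 = 0,
             pitch = cortex$pitch,
             meta = list(cortex = cortex, stimuli = stimuli, hemo = hemo,
                         noise_sd = noise_sd, baseline_in = baseline_in,
                         baseline_out = baseline_out, seed = seed))
}

#' Simulate ultrafast frame blocks
#'
#' Generates complex beamformed frame blocks (200 frames at 500 Hz) with
#' the two-component structure the SVD clutter filter targets: a
#' low-rank (rank <= 3) tissue component with slow sinusoidal drift, at
#' `tissue_amp` times the blood RMS amplitude, plus independent moving
#' blood scatterers whose per-frame phase advance encodes their axial
#' velocity (Doppler shift `2 v f0 / c`). Expected blood power per voxel
#' is proportional to the local scatterer density.
#'
#' @param flow_density Mean scatterers per voxel: a scalar (applied on
#'   the cortex mask if one is given, else everywhere) or an `nz x nx`
#'   matrix.
#' @param n_blocks Number of 1-s-spaced blocks.
#' @param nz,nx Block image dimensions.
#' @param tissue_amp Tissue RMS amplitude as a multiple of blood RMS.
#' @param velocities Axial speed range in mm/s, within (0, 30].
#' @param n_frames,frame_rate Frames per block and frame rate (Hz); the
#'   pulse-repetition frequency is `frame_rate * n_angles` with 15
#'   compounding angles (-14..14 degrees, 2-degree steps).
#' @param f0 Ultrasound centre frequency (Hz), `c0` speed of sound (m/s).
#' @param seed Integer seed.
#' @return List of `fus_frame_block` objects with `t0` at 1-s spacing.
#' @export
simulate_frame_blocks <- function(flow_density, n_blocks = 1,
                                  nz = 16, nx = 16,
                                  tissue_amp = 30,
                                  velocities = c(1, 25),
                                  n_frames = 200, frame_rate = 500,
                                  f0 = 15e6, c0 = 1540,
                                  seed = 1) {
  if (any(flow_density < 0)) stop("flow_density < 0")
  stopifnot(all(velocities > 0), all(velocities <= 30),
            velocities[1] <= velocities[2])
  withr_seed(seed)
  dens <- if (is.matrix(flow_density)) {
    stopifnot(all(dim(flow_density) == c(nz, nx)))
    flow_density
  } else matrix(flow_density, nz, nx)
  npix <- nz * nx
  tt <- (seq_len(n_frames) - 1) / frame_rate

  # fixed tissue spatial modes for the whole run (smooth low-order fields)
  u_modes <- sapply(1:3, function(r) {
    gz <- cos(2 * pi * r * (seq_len(nz) - 1) / nz + stats::runif(1, 0, 2 * pi))
    gx <- cos(2 * pi * r * (seq_len(nx) - 1) / nx + stats::runif(1, 0, 2 * pi))
    as.vector(gz %o% gx) / sqrt(npix)
  })
  u_modes <- apply(u_modes, 2, function(u) u / sqrt(sum(u^2)))
  blood_rms <- sqrt(max(mean(dens), 1e-12))

  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    X <- matrix(0 + 0i, npix, n_frames)
    # blood: Poisson scatterer count per voxel, random phase + velocity
    nsc <- stats::rpois(npix, as.vector(dens))
    tot <- sum(nsc)
    if (tot > 0) {
      vox <- rep.int(seq_len(npix), nsc)
      v <- stats::runif(tot, velocities[1], velocities[2]) *
        sample(c(-1, 1), tot, replace = TRUE)
      fd <- 2 * (v * 1e-3) * f0 / c0       # Doppler shift, Hz
      phi0 <- stats::runif(tot, 0, 2 * pi)
      ph <- outer(fd, tt) * 2 * pi + phi0  # tot x n_frames
      sig <- exp(1i * ph)
      blood <- rowsum(Re(sig), vox, reorder = FALSE) +
        1i * rowsum(Im(sig), vox, reorder = FALSE)
      X[unique(vox), ] <- X[unique(vox), , drop = FALSE] + blood
    }
    # tissue: rank <= 3 slow sinusoidal drift, scaled to tissue_amp x
    # blood RMS (per-voxel RMS, averaged over the plane). The drift
    # parameters are drawn even at tissue_amp = 0 so that a blood-only
    # twin generated from the same seed has identical scatterers.
    fr <- stats::runif(3, 0.3, 2)
    ph <- stats::runif(3, 0, 2 * pi)
    if (tissue_amp > 0) {
      for (r in 1:3) {
        vt <- exp(1i * (2 * pi * fr[r] * tt + ph[r]))
        a_r <- tissue_amp * blood_rms * sqrt(npix) / sqrt(3)
        X <- X + (a_r * u_modes[, r]) %o% vt
      }
    }
    blocks[[b]] <- frame_block(array(X, c(nz, nx, n_frames)),
                               frame_rate = frame_rate, t0 = b - 1)
  }
  attr(blocks, "flow_density") <- dens
  blocks
}
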