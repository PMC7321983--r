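#' Ultrafast frame block
#'
#' One acquisition block of compounded complex frames from which a
#' single power-Doppler image is formed. The acquisition arithmetic is
#' validated on construction: with 15 plane-wave angles spanning -14 to
#' 14 degrees in 2-degree steps and a pulse-repetition frequency of
#' 7,500 Hz, the compounded frame rate is `prf / n_angles = 500` Hz, and
#' 200 frames span `200 / 500 = 0.4` s of each 1-s slot.
#'
#' @param frames Complex array `nz x nx x n_frames`.
#' @param frame_rate Compounded frame rate (Hz).
#' @param prf Pulse-repetition frequency (Hz).
#' @param angles Plane-wave tilt angles (degrees).
#' @param t0 Block start time (s).
#' @return An object of class `fus_frame_block`.
#' @export
frame_block <- function(frames, frame_rate = 500, prf = 7500,
                        angles = seq(-14, 14, by = 2), t0 = 0) {
  stopifnot(length(dim(frames)) == 3)
  n_angles <- length(angles)
  step <- if (n_angles > 1) diff(angles)[1] else NA_real_
  if (n_angles > 1 &&
      abs((max(angles) - min(angles)) / step + 1 - n_angles) > 1e-9) {
    stop("angles must be evenly spaced")
  }
  if (abs(frame_rate - prf / n_angles) > 1e-9) {
    stop("frame_rate must equal prf / n_angles")
  }
  n_frames <- dim(frames)[3]
  structure(list(frames = frames,
                 frame_rate = frame_rate, prf = prf,
                 n_angles = n_angles, angles = angles,
                 block_duration = n_frames / frame_rate,
                 t0 = t0),
            class = "fus_frame_block")
}

#' @export
print.fus_frame_block <- function(x, ...) {
  d <- dim(x$frames)
  cat("<fus_frame_block> ", d[1], "x", d[2], " pixels, ", d[3],
      " frames at ", x$frame_rate, " Hz (", x$block_duration,
      " s, t0 = ", x$t0, " s)\n", sep = "")
  invisible(x)
}

#' Casorati matrix of a frame block
#'
#' Reshapes the block into the space-by-time matrix on which the SVD
#' clutter filter operates: column `t` is frame `t` flattened
#' column-major, so reshaping back is lossless.
#'
#' @param block A [frame_block()].
#' @return Complex matrix `(nz * nx) x n_frames`.
#' @export
casorati <- function(block) {
  if (anyNA(block$frames)) stop("NaN frames")
  d <- dim(block$frames)
  matrix(block$frames, d[1] * d[2], d[3])
}

#' SVD clutter filter
#'
#' Removes tissue-motion clutter by subtracting the `n_cut` leading
#' singular components of the Casorati matrix. Slow, spatially coherent
#' tissue signal concentrates in the first singular vectors; blood
#' scatterer signal, being spatiotemporally incoherent, spreads over the
#' rest. Energy bookkeeping holds exactly: the squared Frobenius norm of
#' the input equals that of the output plus the sum of the removed
#' squared singular values.
#'
#' @param block A [frame_block()].
#' @param n_cut Number of leading singular components to remove
#'   (`0 <= n_cut < n_frames`); `"elbow"` selects the cut automatically
#'   at the maximum curvature of the log singular-value curve.
#' @return The filtered block (same class and metadata), with attributes
#'   `n_cut` and `singular_values`.
#' @export
svd_clutter_filter <- function(block, n_cut) {
  d <- dim(block$frames)
  if (identical(n_cut, "elbow")) {
    n_cut <- elbow_cut(svd(casorati(block), nu = 0, nv = 0)$d)
  }
  if (n_cut >= d[3]) stop("n_cut must be < number of frames")
  stopifnot(n_cut >= 0)
  if (n_cut == 0) {
    out <- block
    attr(out, "n_cut") <- 0L
    return(out)
  }
  C <- casorati(block)
  sv <- svd(C, nu = n_cut, nv = n_cut)
  Cf <- C - sv$u %*% (sv$d[seq_len(n_cut)] * Conj(t(sv$v)))
  out <- block
  out$frames <- array(Cf, d)
  attr(out, "n_cut") <- as.integer(n_cut)
  attr(out, "singular_values") <- sv$d
  out
}

# Elbow of a singular-value curve: maximum second difference of log
# magnitude (interior points only).
elbow_cut <- function(d) {
  ld <- log(pmax(d, .Machine$double.eps))
  if (length(ld) < 3) return(1L)
  curv <- diff(ld, differences = 2)
  as.integer(which.max(curv))
}

#' Power-Doppler image of a (filtered) block
#'
#' Per-pixel mean squared magnitude over the frames of the block. After
#' clutter filtering this is proportional to the number of moving blood
#' scatterers in the voxel, i.e. to cerebral blood volume.
#'
#' @param block A [frame_block()], normally already clutter-filtered.
#' @return Real nonnegative `nz x nx` matrix.
#' @export
power_doppler <- function(block) {
  d <- dim(block$frames)
  m <- matrix(rowMeans(abs(matrix(block$frames, d[1] * d[2], d[3]))^2),
              d[1], d[2])
  m
}

#' Form a 1-Hz power-Doppler series from frame blocks
#'
#' Clutter-filters each block and averages its frames into one Doppler
#' image, giving one image per second. Blocks must be time-ordered at
#' 1-s spacing; gaps are tolerated but the affected frames are flagged
#' in the metadata.
#'
#' @param blocks List of [frame_block()]s with `t0` at 1-s spacing.
#' @param n_cut Clutter-filter cut (see [svd_clutter_filter()]).
#' @return A `fus_series` (`dt = 1`) whose metadata records `n_cut` and
#'   any flagged frames.
#' @export
doppler_series <- function(blocks, n_cut) {
  t0s <- vapply(blocks, function(b) b$t0, numeric(1))
  if (is.unsorted(t0s, strictly = TRUE)) stop("blocks must be time-ordered")
  gaps <- which(abs(diff(t0s) - 1) > 1e-9) + 1L
  imgs <- lapply(blocks, function(b)
    power_doppler(svd_clutter_filter(b, n_cut)))
  d <- dim(blocks[[1]]$frames)
  arr <- array(unlist(imgs, use.names = FALSE),
               c(d[1], d[2], length(blocks)))
  new_series(arr, dt = 1, t0 = t0s[1],
             meta = list(n_cut = n_cut,
                         block_duration = blocks[[1]]$block_duration,
                         flagged_frames = gaps))
}
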