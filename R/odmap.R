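#' Standardize an activation map
#'
#' Z-scores the map over a region: zero mean, unit SD. Affine-invariant,
#' so contralateral and ipsilateral maps become comparable before
#' subtraction regardless of their overall response level.
#'
#' @param map A `fus_activation_map` or numeric matrix.
#' @param region Logical mask over which mean/SD are taken (default: all
#'   finite pixels). Must hold > 1 pixel with nonzero variance.
#' @return Numeric matrix, z-scored over `region` (`NA` elsewhere).
#' @export
standardize_map <- function(map, region = NULL) {
  v <- if (inherits(map, "fus_activation_map")) map$values else map
  region <- region %||% is.finite(v)
  if (sum(region) < 2) stop("region must have > 1 pixel")
  mu <- mean(v[region]); s <- stats::sd(v[region])
  if (!is.finite(s) || s == 0) stop("zero variance in region")
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[region] <- (v[region] - mu) / s
  out
}

new_od_map <- function(od_index, crop, provenance) {
  structure(list(od_index = od_index, crop = crop,
                 provenance = provenance),
            class = "fus_od_map")
}

#' @export
print.fus_od_map <- function(x, ...) {
  cat("<fus_od_map> ", sum(x$crop), " pixels in crop; provenance: ",
      x$provenance, "\n", sep = "")
  invisible(x)
}

#' Ocular-dominance map from standardized eye maps
#'
#' The OD index is the standardized contralateral map minus the
#' standardized ipsilateral map, restricted to the crop region.
#' Antisymmetric by construction: swapping the eyes flips the sign.
#'
#' @param contra_z,ipsi_z Z-scored maps ([standardize_map()]) on the
#'   same geometry.
#' @param crop Logical crop mask (default: jointly finite pixels).
#' @return A `fus_od_map`.
#' @export
od_map <- function(contra_z, ipsi_z, crop = NULL) {
  stopifnot(all(dim(contra_z) == dim(ipsi_z)))
  crop <- crop %||% (is.finite(contra_z) & is.finite(ipsi_z))
  od <- matrix(NA_real_, nrow(contra_z), ncol(contra_z))
  od[crop] <- contra_z[crop] - ipsi_z[crop]
  new_od_map(od, crop, "true")
}

#' OD map from a trial tensor
#'
#' Convenience path from an epoched OD-protocol tensor to the OD map:
#' per-eye activation maps over the OD response window, standardized
#' over the crop, then subtracted.
#'
#' @param tensor A `fus_trial_tensor` containing trials of both eyes
#'   (conditions with `value` +1 = contralateral, -1 = ipsilateral in
#'   the attached stimulus set).
#' @param crop Logical crop mask (e.g. the cortical ribbon).
#' @param window Response window (default the OD 2.5--3.5-s window).
#' @return A `fus_od_map`.
#' @export
od_map_from_tensor <- function(tensor, crop = NULL, window = "od") {
  stim <- tensor$meta$stimuli
  contra_id <- stim$condition_id[stim$value > 0]
  ipsi_id <- stim$condition_id[stim$value < 0]
  mc <- activation_map(tensor, condition = contra_id, window = window)
  mi <- activation_map(tensor, condition = ipsi_id, window = window)
  crop <- crop %||% (is.finite(mc$values) & is.finite(mi$values))
  od_map(standardize_map(mc, crop), standardize_map(mi, crop), crop)
}

#' Even/odd shuffle control map
#'
#' Null-control counterpart of the OD map: trials of both eyes pooled
#' in time order, even-position trials averaged into one activation map
#' and odd-position trials into another, then standardized and
#' subtracted through the same path as the true map. Any consistent
#' eye-specific signal cancels, so columnar structure in the result
#' reflects noise. With an odd total trial count the split differs by
#' one trial; no trial is discarded.
#'
#' @inheritParams od_map_from_tensor
#' @return A `fus_od_map` with provenance `"shuffled"`.
#' @export
shuffle_control <- function(tensor, crop = NULL, window = "od") {
  ord <- order(tensor$t_onset)
  if (length(ord) < 4) stop("need >= 2 trials per parity")
  even <- ord[seq_along(ord) %% 2 == 0]
  odd <- ord[seq_along(ord) %% 2 == 1]
  m1 <- activation_map(tensor, trials = even, window = window)
  m2 <- activation_map(tensor, trials = odd, window = window)
  crop <- crop %||% (is.finite(m1$values) & is.finite(m2$values))
  out <- od_map(standardize_map(m1, crop), standardize_map(m2, crop), crop)
  out$provenance <- "shuffled"
  out
}

# Signed distances of query points to a dense path, normal oriented by
# `orient` (+1 keeps the normal with positive mean z-component).
signed_distance_to_path <- function(query, dense) {
  idx <- nearest_on_polyline(query, dense$points)
  tang <- dense$tangent[idx, , drop = FALSE]
  nrm <- cbind(-tang[, 2], tang[, 1])
  if (sum(nrm[, 2]) < 0) nrm <- -nrm
  dvec <- query - dense$points[idx, , drop = FALSE]
  list(dist = rowSums(dvec * nrm), idx = idx,
       interior = idx > 1 & idx < nrow(dense$points))
}

#' Layer segmentation between cortical boundary paths
#'
#' Given the manually indicated top (pial) and bottom (white-matter)
#' boundary polylines, assigns each pixel a relative depth -- its signed
#' distance to the top path over the sum of distances to both paths,
#' measured along the local path normals -- and a laminar label via the
#' depth-fraction scheme. An arc-length coordinate along the mid-curve
#' between the paths is attached for laminar profiles.
#'
#' @param top,bottom Two-column (x, z) polylines in mm; must not cross.
#' @param nz,nx Image dimensions.
#' @param pitch_z,pitch_x Pixel pitch in mm.
#' @param fractions Laminar depth fractions ([haessler_fractions()]).
#' @return Object of class `fus_layer_seg`: matrices `depth` (0 at pia,
#'   1 at white matter), `layer` (factor levels I..VI/none), logical
#'   `inside`, and `arc_length` (um along the mid-curve).
#' @export
segment_layers <- function(top, bottom, nz = 98, nx = 128,
                           pitch_z = 0.1, pitch_x = 0.11,
                           fractions = haessler_fractions()) {
  dtop <- densify_polyline(top, pitch = min(pitch_z, pitch_x) / 2)
  dbot <- densify_polyline(bottom, pitch = min(pitch_z, pitch_x) / 2)
  # crossing check on matched relative arc length
  u <- seq(0, 1, length.out = 200)
  tp <- cbind(stats::approx(dtop$s / dtop$length, dtop$points[, 1], u)$y,
              stats::approx(dtop$s / dtop$length, dtop$points[, 2], u)$y)
  bp <- cbind(stats::approx(dbot$s / dbot$length, dbot$points[, 1], u)$y,
              stats::approx(dbot$s / dbot$length, dbot$points[, 2], u)$y)
  gap <- bp - tp
  dir <- colMeans(gap)
  if (any(rowSums(gap * rep(dir / sqrt(sum(dir^2)), each = nrow(gap))) <= 0)) {
    stop("crossing paths")
  }
  mid <- (tp + bp) / 2
  dmid <- densify_polyline(mid, pitch = min(pitch_z, pitch_x) / 2)

  grid <- pixel_grid(nz, nx, pitch_z, pitch_x)
  query <- cbind(as.vector(grid$xx), as.vector(grid$zz))
  st <- signed_distance_to_path(query, dtop)
  sb <- signed_distance_to_path(query, dbot)
  # top normal oriented towards bottom, bottom normal away from top:
  # depth grows from the top path towards the bottom path
  if (mean(sb$dist[st$dist > 0]) > 0) sb$dist <- sb$dist  # keep
  inside_v <- st$interior & sb$interior & st$dist >= 0 & sb$dist <= 0
  depth_v <- ifelse(inside_v,
                    st$dist / (st$dist + pmax(-sb$dist, 0)), NA_real_)
  arc_idx <- nearest_on_polyline(query, dmid$points)
  arc_v <- ifelse(inside_v, dmid$s[arc_idx] * 1000, NA_real_)
  shape <- function(v) matrix(v, nz, nx)
  structure(list(depth = shape(depth_v),
                 layer = matrix(assign_layers(depth_v, fractions), nz, nx),
                 inside = shape(inside_v) > 0,
                 arc_length = shape(arc_v),
                 fractions = fractions,
                 pitch = c(z = pitch_z, x = pitch_x)),
            class = "fus_layer_seg")
}

#' Laminar OD-index profile
#'
#' Collects the OD index of the pixels of one layer (optionally within
#' an ROI) along the arc-length coordinate, centers it, resamples it on
#' a uniform pitch (bin means), and fits a least-squares smoothing
#' spline (smoothing chosen by generalized cross-validation unless
#' `spar` is given). The distance origin is the left edge of the
#' profile (the first intracortical column).
#'
#' @param od A `fus_od_map` (or numeric matrix of OD indices).
#' @param seg A [segment_layers()] segmentation (a [make_cortex()] scene
#'   also works: its ground-truth layers and arc lengths are used).
#' @param layer Layer label (`"I"`, `"II/III"`, `"IV"`, `"V"`, `"VI"`).
#' @param roi Optional logical ROI mask.
#' @param pitch_um Resampling pitch along the layer (um).
#' @param spar Optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return A tibble of class `fus_layer_profile`: `distance` (um from
#'   the profile's left edge), `od_raw` (centered bin means), `od_fit`
#'   (spline values).
#' @export
layer_profile <- function(od, seg, layer = "IV", roi = NULL,
                          pitch_um = 100, spar = NULL) {
  odv <- if (inherits(od, "fus_od_map")) od$od_index else od
  if (inherits(seg, "fus_cortex")) {
    lay <- seg$layer_index; arc <- seg$arc_length; inside <- seg$mask
  } else {
    lay <- seg$layer; arc <- seg$arc_length; inside <- seg$inside
  }
  sel <- inside & lay == layer & is.finite(odv) & is.finite(arc)
  if (!is.null(roi)) sel <- sel & roi
  if (sum(sel) < 10) stop("fewer than 10 samples in layer profile")
  s <- arc[sel]; y <- odv[sel]
  y <- y - mean(y)                       # centered profile
  grid <- seq(min(s), max(s), by = pitch_um)
  bin <- round((s - min(s)) / pitch_um) + 1
  raw <- rep(NA_real_, length(grid))
  agg <- tapply(y, bin, mean)
  raw[as.integer(names(agg))] <- agg
  if (anyNA(raw)) {
    raw <- stats::approx(grid[!is.na(raw)], raw[!is.na(raw)],
                         xout = grid, rule = 2)$y
  }
  sp <- if (is.null(spar)) {
    stats::smooth.spline(s, y, cv = FALSE)
  } else {
    stats::smooth.spline(s, y, spar = spar)
  }
  fit <- stats::predict(sp, grid)$y
  out <- tibble::tibble(distance = grid - min(s),
                        od_raw = raw, od_fit = fit)
  attr(out, "pitch_um") <- pitch_um
  attr(out, "layer") <- layer
  attr(out, "n_points") <- length(s)
  class(out) <- c("fus_layer_profile", class(out))
  out
}

# Topographic prominence of the peaks of y (indices `peaks`): descend
# from each peak to the nearest higher ground on each side; the base is
# the higher of the two interval minima.
peak_prominence <- function(y, peaks) {
  n <- length(y)
  vapply(peaks, function(i) {
    h <- y[i]
    lhs <- if (i > 1) {
      higher <- which(y[seq_len(i - 1)] > h)
      lo <- if (length(higher)) max(higher) + 1 else 1
      min(y[lo:(i - 1)])
    } else h
    rhs <- if (i < n) {
      higher <- which(y[(i + 1):n] > h) + i
      hi <- if (length(higher)) min(higher) - 1 else n
      min(y[(i + 1):hi])
    } else h
    h - max(lhs, rhs)
  }, numeric(1))
}

#' Local extrema of a laminar profile
#'
#' Finds local maxima of the spline-fitted profile with topographic
#' prominence of at least `min_prominence` OD-index units and absolute
#' value above `min_abs`; minima are found symmetrically on the negated
#' profile. Peak finding runs on the spline fit, not the raw bins.
#'
#' @param profile A [layer_profile()].
#' @param min_prominence Minimal peak prominence (OD index).
#' @param min_abs Minimal absolute extremum value (OD index).
#' @return List with tibbles `maxima` and `minima` (`index`, `distance`,
#'   `value`, `prominence`); either may be empty.
#' @export
find_extrema <- function(profile, min_prominence = 0.75, min_abs = 0.25) {
  y <- profile$od_fit
  one_side <- function(y, sign_label) {
    n <- length(y)
    cand <- which(diff(sign(diff(y))) < 0) + 1
    if (!length(cand)) {
      return(tibble::tibble(index = integer(), distance = numeric(),
                            value = numeric(), prominence = numeric()))
    }
    prom <- peak_prominence(y, cand)
    keep <- prom >= min_prominence &
      (if (sign_label > 0) y[cand] > min_abs else TRUE)
    cand <- cand[keep]; prom <- prom[keep]
    tibble::tibble(index = cand, distance = profile$distance[cand],
                   value = sign_label * y[cand], prominence = prom)
  }
  maxima <- one_side(y, 1)
  minima <- one_side(-y, -1)
  minima <- minima[minima$value < -min_abs, , drop = FALSE]
  list(maxima = maxima, minima = minima)
}

#' Mean OD bandwidth from profile extrema
#'
#' Half-distances between consecutive maxima and between consecutive
#' minima, pooled; their mean estimates the OD band width (one band per
#' half-period of the columnar oscillation).
#'
#' @param extrema Output of [find_extrema()].
#' @return List with `mean_um`, `sem_um` (0 with `single_interval =
#'   TRUE` when only one half-distance is available), `n_intervals`,
#'   and the pooled `half_distances`.
#' @export
mean_bandwidth <- function(extrema) {
  hd <- c(if (nrow(extrema$maxima) >= 2) diff(extrema$maxima$distance) / 2,
          if (nrow(extrema$minima) >= 2) diff(extrema$minima$distance) / 2)
  if (!length(hd)) stop("insufficient extrema: need >= 2 maxima or minima")
  list(mean_um = mean(hd),
       sem_um = if (length(hd) > 1) sem(hd) else 0,
       single_interval = length(hd) == 1,
       n_intervals = length(hd),
       half_distances = hd)
}

#' Spatial-frequency spectrum of a laminar profile
#'
#' One-sided magnitude spectrum (FFT) of the uniformly resampled,
#' centered profile, filtered with a centered 3-sample moving average
#' and normalized by its maximum. The frequency axis is in inverse
#' micrometres; no zero padding is applied.
#'
#' @param profile A [layer_profile()].
#' @param use Which profile column to transform: the resampled data
#'   (`"od_raw"`, default) or the spline fit.
#' @return A tibble of class `fus_spectrum`: `frequency` (um^-1),
#'   `magnitude` (max-normalized).
#' @export
layer_spectrum <- function(profile, use = c("od_raw", "od_fit")) {
  use <- match.arg(use)
  y <- profile[[use]]
  pitch <- attr(profile, "pitch_um")
  if (is.null(pitch)) stop("non-uniform sampling: profile lacks a pitch")
  if (anyNA(y)) stop("profile contains missing samples")
  n <- length(y)
  nh <- floor(n / 2) + 1
  mag <- Mod(stats::fft(y))[seq_len(nh)]
  sm <- mag
  if (nh >= 2) {
    for (i in seq_len(nh)) {
      lo <- max(1, i - 1); hi <- min(nh, i + 1)
      sm[i] <- mean(mag[lo:hi])
    }
  }
  if (max(sm) > 0) sm <- sm / max(sm)
  out <- tibble::tibble(frequency = (seq_len(nh) - 1) / (n * pitch),
                        magnitude = sm)
  attr(out, "pitch_um") <- pitch
  class(out) <- c("fus_spectrum", class(out))
  out
}

#' Band-limited spectral index
#'
#' Fraction of the (smoothed, max-normalized) magnitude spectrum lying
#' in the spatial-frequency band of classical OD bands: `1/(2*700)` to
#' `1/(2*350)` um^-1 for 350--700-um bands. The zero-frequency bin is
#' included in the denominator.
#'
#' @param spectrum A [layer_spectrum()].
#' @param band `c(low, high)` in um^-1.
#' @return Fraction in `[0, 1]`.
#' @export
spectral_index <- function(spectrum, band = od_band()) {
  f <- spectrum$frequency
  if (band[1] > max(f)) stop("band outside the frequency axis")
  inb <- f >= band[1] & f <= band[2]
  tot <- sum(spectrum$magnitude)
  if (tot == 0) return(0)
  sum(spectrum$magnitude[inb]) / tot
}

#' Classical OD spatial-frequency band
#'
#' Band endpoints for 350--700-um OD bands: `1/(2*700)` and
#' `1/(2*350)` um^-1 (one full period spans two bands).
#'
#' @return `c(low, high)` in um^-1.
#' @export
od_band <- function() c(1 / (2 * 700), 1 / (2 * 350))

#' Spectral index per layer per ROI
#'
#' Laminar selectivity table: the band-limited spectral index of the
#' OD-index profile of every layer in every ROI. Layers with too few
#' pixels yield `NA` (flagged missing cells).
#'
#' @param od A `fus_od_map` (or matrix).
#' @param seg A [segment_layers()] segmentation or [make_cortex()] scene.
#' @param rois Named list of logical ROI masks (default one whole-map
#'   ROI).
#' @param layers Layer labels to profile.
#' @param pitch_um Resampling pitch (um).
#' @param band Spectral band (um^-1).
#' @return Tibble with columns `roi`, `layer`, `spectral_index`.
#' @export
layer_selectivity_table <- function(od, seg, rois = NULL,
                                    layers = c("I", "II/III", "IV",
                                               "V", "VI"),
                                    pitch_um = 100, band = od_band()) {
  rois <- rois %||% list(all = NULL)
  purrr::map_dfr(names(rois), function(rn) {
    purrr::map_dfr(layers, function(ly) {
      idx <- tryCatch({
        pr <- layer_profile(od, seg, layer = ly, roi = rois[[rn]],
                            pitch_um = pitch_um)
        spectral_index(layer_spectrum(pr), band)
      }, error = function(e) NA_real_)
      tibble::tibble(roi = rn, layer = ly, spectral_index = idx)
    })
  })
}
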