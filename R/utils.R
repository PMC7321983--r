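#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# Resample a polyline (n x 2 matrix, mm) at approximately `pitch` mm,
# returning points, cumulative arc length and unit tangents.
densify_polyline <- function(path, pitch = 0.025) {
  stopifnot(is.matrix(path), ncol(path) == 2, nrow(path) >= 2)
  seg <- diff(path)
  len <- sqrt(rowSums(seg^2))
  if (any(len == 0)) stop("degenerate polyline segment")
  s_knot <- c(0, cumsum(len))
  total <- s_knot[length(s_knot)]
  s <- seq(0, total, by = pitch)
  if (s[length(s)] < total) s <- c(s, total)
  x <- stats::approx(s_knot, path[, 1], xout = s)$y
  z <- stats::approx(s_knot, path[, 2], xout = s)$y
  pts <- cbind(x, z)
  tang <- rbind(pts[2, ] - pts[1, ], pts[-1, ] - pts[-nrow(pts), ])
  tang <- tang / sqrt(rowSums(tang^2))
  list(points = pts, s = s, tangent = tang, length = total)
}

# Nearest dense-polyline sample for each query point (m x 2), chunked to
# bound memory. Returns index vector.
nearest_on_polyline <- function(query, pts, chunk = 2000L) {
  m <- nrow(query)
  idx <- integer(m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    dx <- outer(query[lo:hi, 1], pts[, 1], "-")
    dz <- outer(query[lo:hi, 2], pts[, 2], "-")
    idx[lo:hi] <- max.col(-(dx * dx + dz * dz), ties.method = "first")
  }
  idx
}

# Pixel-centre coordinates (mm) of the imaging grid.
# Rows index depth (z, pitch mm), columns lateral position (x).
pixel_grid <- function(nz, nx, pitch_z = 0.1, pitch_x = 0.11) {
  z <- (seq_len(nz) - 0.5) * pitch_z
  x <- (seq_len(nx) - 0.5) * pitch_x
  list(z = z, x = x,
       zz = matrix(z, nz, nx), xx = matrix(x, nz, nx, byrow = TRUE))
}

# Standard error of the mean.
sem <- function(x) stats::sd(x) / sqrt(length(x))
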