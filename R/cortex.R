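#' Hidden-layer depth-fraction table (Haessler-style scheme)
#'
#' Default laminar boundaries as fractions of cortical depth (0 = pial
#' surface, 1 = white-matter boundary). The scheme indexes depth into
#' layers I, II/III, IV, V and VI; the fractions are configurable because
#' published laminar schemes give qualitative, not numeric, boundaries.
#'
#' @return Named numeric vector of upper boundaries for layers
#'   `I`, `II/III`, `IV`, `V`, `VI` (lower boundary of the first is 0).
#' @export
haessler_fractions <- function() {
  c("I" = 0.08, "II/III" = 0.35, "IV" = 0.60, "V" = 0.80, "VI" = 1.00)
}

layer_levels <- function() c("I", "II/III", "IV", "V", "VI", "none")

assign_layers <- function(depth_fraction, fractions = haessler_fractions()) {
  if (abs(fractions[length(fractions)] - 1) > 1e-9 ||
      is.unsorted(fractions, strictly = TRUE)) {
    stop("layer fractions must strictly increase and end at 1")
  }
  idx <- findInterval(pmin(pmax(depth_fraction, 0), 1),
                      c(-Inf, fractions[-length(fractions)]))
  out <- names(fractions)[idx]
  out[is.na(depth_fraction)] <- "none"
  factor(out, levels = layer_levels())
}

#' Default folded cortical-ribbon midline
#'
#' A gentle polyline path (lateral x, depth z, in mm) emulating a patch
#' of superficial cortex descending into a calcarine-like fold, sized for
#' the 14 x 10 mm imaging plane.
#'
#' @param nx_mm,depth_mm Plane extent in mm.
#' @return A two-column matrix (x, z) in mm.
#' @export
default_ribbon_path <- function(nx_mm = 14.08, depth_mm = 9.8) {
  x <- seq(0.6, nx_mm - 0.6, length.out = 60)
  z <- 2.2 + 3.4 * exp(-((x - nx_mm / 2) / 2.6)^2)
  cbind(x, z)
}

#' Generate a ground-truth cortical scene
#'
#' Builds the synthetic cortical model the generator and recovery tests
#' run on: a ribbon of configurable thickness around a midline polyline,
#' with per-pixel depth fraction, laminar index, arc-length coordinate
#' along the ribbon, smooth eccentricity and polar-angle preference
#' gradients, and a square-wave ocular-dominance (OD) phase whose sign
#' alternates every `od_column_width` micrometres of arc length (so one
#' left-eye plus one right-eye band spans two column widths). OD
#' modulation depth is laminar, set by `od_layer_gain`.
#'
#' @param nz,nx Image dimensions (depth rows x lateral columns).
#' @param pitch_z,pitch_x Pixel pitch in mm (depth 0.1, lateral 0.11).
#' @param path Midline polyline, two-column (x, z) matrix in mm.
#' @param thickness_mm Cortical thickness in mm.
#' @param od_column_width Width of one OD band in micrometres; must
#'   exceed twice the depth pixel pitch or columns are unresolvable.
#' @param od_layer_gain Named vector of OD modulation depth in `[0, 1]`
#'   per layer (`I`, `II/III`, `IV`, `V`, `VI`).
#' @param ecc_range Eccentricity preference range mapped linearly along
#'   the ribbon (DVA).
#' @param ang_range Polar-angle preference range (degrees).
#' @param layer_fractions Laminar depth-fraction table
#'   ([haessler_fractions()]).
#' @param seed Unused at present (geometry is deterministic); kept so all
#'   generator entry points share a seeding convention.
#' @return An object of class `fus_cortex`: list of image matrices
#'   (`mask`, `depth_fraction`, `layer_index`, `arc_length` in um,
#'   `ecc_pref`, `ang_pref`, `od_phase`) plus geometry metadata.
#' @export
make_cortex <- function(nz = 98, nx = 128,
                        pitch_z = 0.1, pitch_x = 0.11,
                        path = default_ribbon_path(nx * pitch_x,
                                                   nz * pitch_z),
                        thickness_mm = 1.6,
                        od_column_width = 500,
                        od_layer_gain = c("I" = 0.1, "II/III" = 0.5,
                                          "IV" = 1, "V" = 0.5,
                                          "VI" = 0.1),
                        ecc_range = c(1.5, 15),
                        ang_range = c(0, 180),
                        layer_fractions = haessler_fractions(),
                        seed = NULL) {
  stopifnot(thickness_mm > 0)
  if (od_column_width <= 2 * pitch_z * 1000) {
    stop("unresolvable columns: od_column_width must exceed twice the ",
         "depth pixel pitch (", 2 * pitch_z * 1000, " um)")
  }
  dense <- densify_polyline(path, pitch = min(pitch_z, pitch_x) / 4)
  grid <- pixel_grid(nz, nx, pitch_z, pitch_x)
  query <- cbind(as.vector(grid$xx), as.vector(grid$zz))
  idx <- nearest_on_polyline(query, dense$points)

  # signed normal distance; normal oriented towards increasing depth
  tang <- dense$tangent[idx, , drop = FALSE]
  nrm <- cbind(-tang[, 2], tang[, 1])
  flip <- sign(sum(nrm[, 2]))
  if (flip < 0) nrm <- -nrm
  dvec <- query - dense$points[idx, , drop = FALSE]
  d <- rowSums(dvec * nrm)

  interior <- idx > 1 & idx < nrow(dense$points)
  mask_v <- interior & abs(d) <= thickness_mm / 2
  depth_v <- ifelse(mask_v, 0.5 + d / thickness_mm, NA_real_)
  arc_v <- ifelse(mask_v, dense$s[idx] * 1000, NA_real_)

  shape <- function(v) matrix(v, nz, nx)
  mask <- shape(mask_v)
  depth_fraction <- shape(depth_v)
  arc_length <- shape(arc_v)

  total_um <- dense$length * 1000
  frac <- arc_length / total_um
  ecc_pref <- ecc_range[1] + frac * diff(ecc_range)
  ang_pref <- ang_range[1] + frac * diff(ang_range)

  od_phase <- shape(ifelse(
    mask_v, ifelse(floor(arc_v / od_column_width) %% 2 == 0, 1, -1),
    NA_real_))

  layer_index <- matrix(assign_layers(depth_v, layer_fractions), nz, nx)

  structure(list(
    mask = mask,
    depth_fraction = depth_fraction,
    layer_index = layer_index,
    arc_length = arc_length,
    ecc_pref = ecc_pref,
    ang_pref = ang_pref,
    od_phase = od_phase,
    od_column_width = od_column_width,
    od_layer_gain = od_layer_gain,
    layer_fractions = layer_fractions,
    ecc_range = ecc_range,
    ang_range = ang_range,
    thickness_mm = thickness_mm,
    path = path,
    path_length_mm = dense$length,
    pitch = c(z = pitch_z, x = pitch_x, slice = 0.4),
    dim = c(nz = nz, nx = nx)
  ), class = "fus_cortex")
}

#' @export
print.fus_cortex <- function(x, ...) {
  cat("<fus_cortex> ", x$dim["nz"], "x", x$dim["nx"],
      " plane; ", sum(x$mask), " cortical pixels; ",
      "ribbon ", round(x$path_length_mm, 2), " mm x ",
      x$thickness_mm, " mm; OD column width ", x$od_column_width,
      " um\n", sep = "")
  invisible(x)
}

#' Cortical surface and white-matter boundary polylines
#'
#' Offsets the ribbon midline by half the thickness along the local
#' normal, giving the top (pial) and bottom (white-matter) paths that
#' the analysis-side layer segmentation takes as input.
#'
#' @param cortex A [make_cortex()] scene.
#' @return List with two-column (x, z) mm matrices `top` and `bottom`.
#' @export
cortex_boundaries <- function(cortex) {
  dense <- densify_polyline(cortex$path, pitch = 0.05)
  nrm <- cbind(-dense$tangent[, 2], dense$tangent[, 1])
  if (sum(nrm[, 2]) < 0) nrm <- -nrm
  h <- cortex$thickness_mm / 2
  list(top = dense$points - h * nrm, bottom = dense$points + h * nrm)
}
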