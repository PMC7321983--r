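#' Stack per-condition activation maps
#'
#' Assembles the activation maps of one protocol into a 3D array ordered
#' by condition value, the input to per-pixel tuning fits.
#'
#' @param maps List of `fus_activation_map`s (one per condition) with
#'   identical geometry.
#' @param values Condition values (DVA or degrees) in the same order as
#'   `maps`; defaults to looking them up in `stimuli`.
#' @param stimuli Optional [stimulus_set()] used to map the maps'
#'   condition ids to values.
#' @return Object of class `fus_condition_stack`: array
#'   `nz x nx x n_cond` plus sorted `values`.
#' @export
condition_stack <- function(maps, values = NULL, stimuli = NULL) {
  if (length(maps) < 4) stop("need >= 4 conditions")
  dims <- lapply(maps, function(m) dim(m$values))
  if (length(unique(dims)) != 1) stop("mismatched map shapes")
  if (is.null(values)) {
    if (is.null(stimuli)) stop("supply condition values or a stimulus set")
    ids <- vapply(maps, function(m) m$condition_id[1], numeric(1))
    values <- stimuli$value[match(ids, stimuli$condition_id)]
  }
  ord <- order(values)
  arr <- array(unlist(lapply(maps[ord], function(m) m$values),
                      use.names = FALSE),
               c(dims[[1]], length(maps)))
  structure(list(data = arr, values = values[ord]),
            class = "fus_condition_stack")
}

# Gaussian + offset least squares on a (center, width) grid: amplitude
# and offset are linear given the shape, so each grid point is an exact
# 2-parameter solve, vectorised over pixels.
gaussian_grid_fit <- function(Y, values, centers, widths) {
  npix <- nrow(Y)
  Yt <- t(Y)  # ncond x npix
  best <- list(rss = rep(Inf, npix), center = rep(NA_real_, npix),
               width = rep(NA_real_, npix), amp = rep(NA_real_, npix),
               offset = rep(NA_real_, npix))
  for (w in widths) {
    for (ce in centers) {
      g <- exp(-(values - ce)^2 / (2 * w^2))
      if (stats::sd(g) < 1e-8) next
      X <- cbind(1, g)
      P <- solve(crossprod(X), t(X))      # 2 x ncond
      coefs <- P %*% Yt                   # 2 x npix
      rss <- colSums((Yt - X %*% coefs)^2)
      upd <- which(rss < best$rss)
      if (length(upd)) {
        best$rss[upd] <- rss[upd]
        best$center[upd] <- ce
        best$width[upd] <- w
        best$offset[upd] <- coefs[1, upd]
        best$amp[upd] <- coefs[2, upd]
      }
    }
  }
  best
}

#' Per-pixel Gaussian tuning fit
#'
#' Least-squares fit of `offset + amplitude * exp(-(v - center)^2 /
#' (2 width^2))` to the responses of one pixel across conditions, with a
#' deterministic multi-start grid over (center, width) followed by
#' Nelder-Mead refinement (amplitude and offset profiled out exactly).
#' The coefficient of determination is computed against the flat-mean
#' model.
#'
#' @param responses Numeric vector of per-condition responses (% CBV).
#' @param values Condition values (same length, DVA or degrees).
#' @return Object of class `fus_tuning_fit`: `amplitude`, `center`
#'   (clamped to the stimulated range), `width`, `offset`, `r_squared`,
#'   `fitted`.
#' @export
fit_pixel_tuning <- function(responses, values) {
  ok <- is.finite(responses)
  if (sum(ok) < 4) stop("need >= 4 finite responses")
  y <- responses[ok]; v <- values[ok]
  tss <- sum((y - mean(y))^2)
  rng <- range(v)
  if (tss == 0) {
    return(structure(list(amplitude = 0, center = mean(rng),
                          width = diff(rng) / 2, offset = y[1],
                          r_squared = 0, fitted = y),
                     class = "fus_tuning_fit"))
  }
  step <- mean(diff(sort(v)))
  centers <- seq(rng[1], rng[2], length.out = 41)
  widths <- step * c(0.5, 0.75, 1, 1.5, 2, 3)
  g0 <- gaussian_grid_fit(matrix(y, 1), v, centers, widths)
  prof_rss <- function(th) {
    ce <- th[1]; w <- exp(th[2])
    g <- exp(-(v - ce)^2 / (2 * w^2))
    if (stats::sd(g) < 1e-10) return(tss)
    r <- stats::lm.fit(cbind(1, g), y)$residuals
    sum(r^2)
  }
  opt <- stats::optim(c(g0$center, log(g0$width)), prof_rss,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 4000))
  ce <- min(max(opt$par[1], rng[1]), rng[2])
  w <- exp(opt$par[2])
  g <- exp(-(v - ce)^2 / (2 * w^2))
  co <- stats::lm.fit(cbind(1, g), y)
  rss <- sum(co$residuals^2)
  structure(list(amplitude = unname(co$coefficients[2]), center = ce,
                 width = w, offset = unname(co$coefficients[1]),
                 r_squared = 1 - rss / tss,
                 fitted = unname(cbind(1, g) %*% co$coefficients)[, 1]),
            class = "fus_tuning_fit")
}

#' @export
print.fus_tuning_fit <- function(x, ...) {
  cat("<fus_tuning_fit> center ", signif(x$center, 4), ", width ",
      signif(x$width, 4), ", amplitude ", signif(x$amplitude, 4),
      ", R^2 ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_pixel_tuning
#' @param x A `fus_tuning_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fus_tuning_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "center", "width", "offset"),
                 estimate = c(x$amplitude, x$center, x$width, x$offset))
}

#' Raw preference map from a condition stack
#'
#' Fits the Gaussian tuning model at every pixel of the stack (grid
#' search over center and width with exact linear amplitude/offset) and
#' thresholds validity: a pixel is retinotopically valid when its fit
#' explains the data (R^2 above `r2_threshold`), its amplitude is
#' positive, and its center lies strictly inside the stimulated range.
#'
#' @param stack A [condition_stack()].
#' @param r2_threshold Coefficient-of-determination threshold
#'   (default 0.02).
#' @param mask Optional logical analysis mask (e.g. the cortical
#'   ribbon); pixels outside are never fitted.
#' @param center_step Grid step for the center, in condition units
#'   (default one tenth of the condition spacing).
#' @return Object of class `fus_preference_map`: matrices `center`,
#'   `width`, `amplitude`, `r_squared`, logical `valid`, the analysis
#'   `mask`, the stimulated `range`, and a `post_filtered` flag.
#' @export
preference_map <- function(stack, r2_threshold = 0.02, mask = NULL,
                           center_step = NULL) {
  d <- dim(stack$data)
  npix <- d[1] * d[2]
  mask <- mask %||% matrix(TRUE, d[1], d[2])
  Y <- matrix(stack$data, npix, d[3])
  sel <- which(as.vector(mask) & rowSums(!is.finite(Y)) == 0)
  v <- stack$values
  rng <- range(v)
  step <- mean(diff(v))
  center_step <- center_step %||% (step / 10)
  centers <- seq(rng[1], rng[2], by = center_step)
  widths <- step * c(0.5, 0.75, 1, 1.5, 2, 3)
  fit <- gaussian_grid_fit(Y[sel, , drop = FALSE], v, centers, widths)
  tss <- rowSums((Y[sel, , drop = FALSE] -
                    rowMeans(Y[sel, , drop = FALSE]))^2)
  r2 <- ifelse(tss > 0, 1 - fit$rss / tss, 0)
  shape <- function(vals, default = NA_real_) {
    m <- matrix(default, d[1], d[2])
    m[sel] <- vals
    m
  }
  valid_v <- r2 > r2_threshold & fit$amp > 0 &
    fit$center > rng[1] & fit$center < rng[2]
  structure(list(center = shape(ifelse(valid_v, fit$center, NA_real_)),
                 width = shape(ifelse(valid_v, fit$width, NA_real_)),
                 amplitude = shape(fit$amp),
                 r_squared = shape(r2),
                 valid = shape(valid_v, FALSE) > 0,
                 mask = mask, range = rng, values = v,
                 r2_threshold = r2_threshold,
                 post_filtered = FALSE),
            class = "fus_preference_map")
}

#' @export
print.fus_preference_map <- function(x, ...) {
  cat("<fus_preference_map> ", sum(x$valid), " valid pixels of ",
      sum(x$mask), " in mask; range ",
      paste(signif(x$range, 4), collapse = ".."),
      if (x$post_filtered) "; post-filtered" else "", "\n", sep = "")
  invisible(x)
}

median_filter_valid <- function(center, valid) {
  d <- dim(center)
  out <- center
  for (i in which(valid)) {
    r <- ((i - 1) %% d[1]) + 1
    c <- ((i - 1) %/% d[1]) + 1
    rr <- max(1, r - 1):min(d[1], r + 1)
    cc <- max(1, c - 1):min(d[2], c + 1)
    nb <- center[rr, cc]
    nb <- nb[is.finite(nb)]
    out[i] <- stats::median(nb)
  }
  out
}

nearest_valid_fill <- function(center, valid, targets) {
  if (!any(valid) || !length(targets)) return(center)
  d <- dim(center)
  vi <- which(valid)
  vr <- ((vi - 1) %% d[1]) + 1
  vc <- ((vi - 1) %/% d[1]) + 1
  out <- center
  for (i in targets) {
    r <- ((i - 1) %% d[1]) + 1
    c <- ((i - 1) %/% d[1]) + 1
    j <- which.min((vr - r)^2 + (vc - c)^2)
    out[i] <- center[vi[j]]
  }
  out
}

#' Post-filter a preference map
#'
#' The readability filters applied to the raw peak-index map: a 3x3
#' median over valid pixels, nearest-valid interpolation to refill
#' invalid pixels inside the analysis mask, and a lateral 1x3 mean
#' (each pixel averaged with its two lateral neighbours). Pixels outside
#' the mask are untouched, and no filter can move a center outside the
#' stimulated range (all are order statistics or convex averages of
#' in-range values).
#'
#' @param pm A [preference_map()].
#' @return A post-filtered `fus_preference_map` (all mask pixels valid).
#' @export
postprocess_map <- function(pm) {
  d <- dim(pm$center)
  center <- median_filter_valid(pm$center, pm$valid)
  fill_targets <- which(pm$mask & !pm$valid)
  center <- nearest_valid_fill(center, pm$valid, fill_targets)
  # lateral 1x3 mean within the mask, edge/mask-boundary replicate
  sm <- center
  for (i in which(pm$mask)) {
    r <- ((i - 1) %% d[1]) + 1
    c <- ((i - 1) %/% d[1]) + 1
    cc <- c(c - 1, c, c + 1)
    cc <- cc[cc >= 1 & cc <= d[2]]
    vals <- center[r, cc]
    vals <- vals[is.finite(vals)]
    sm[i] <- mean(vals)
  }
  out <- pm
  out$center <- pmin(pmax(sm, pm$range[1]), pm$range[2])
  out$valid <- pm$mask & is.finite(out$center)
  out$post_filtered <- TRUE
  out
}

#' Between-run repeatability of preference maps
#'
#' Percentage of jointly valid pixels whose preferred values agree
#' within `tol` (2 DVA by default).
#'
#' @param mapA,mapB `fus_preference_map`s on the same geometry.
#' @param tol Agreement tolerance in condition units.
#' @return Percentage in `[0, 100]`.
#' @export
repeatability <- function(mapA, mapB, tol = 2) {
  stopifnot(all(dim(mapA$center) == dim(mapB$center)))
  both <- mapA$valid & mapB$valid
  if (!any(both)) stop("no jointly valid pixels")
  100 * mean(abs(mapA$center[both] - mapB$center[both]) <= tol)
}
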