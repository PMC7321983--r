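#' Write / read a Doppler series container
#'
#' A light named-array container: a directory holding `meta.json`
#' (dimensions, sampling, pixel pitch, free-form metadata) and one raw
#' little-endian float64 file per dataset. Round-trips a `fus_series`
#' losslessly.
#'
#' @param series A `fus_series`.
#' @param path Container directory (created if needed).
#' @return `read_series()` returns a `fus_series`.
#' @export
write_series <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(series$images)
  meta <- list(datasets = list(images = list(dim = d, dtype = "float64")),
               dt = series$dt, t0 = series$t0,
               pitch = as.list(series$pitch),
               n_cut = series$meta$n_cut)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "images.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(series$images), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  d <- meta$datasets$images$dim
  con <- file(file.path(path, "images.bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  new_series(array(v, d), dt = meta$dt, t0 = meta$t0,
             pitch = unlist(meta$pitch),
             meta = list(n_cut = meta$n_cut))
}

#' Export maps as multi-page TIFF
#'
#' Writes one or more image matrices as a (multi-page) 32-bit float
#' TIFF. Requires the `tiff` package.
#'
#' @param maps A matrix or list of matrices (`NA` written as 0).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_map_tiff <- function(maps, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export")
  }
  if (is.matrix(maps)) maps <- list(maps)
  pages <- lapply(maps, function(m) {
    m[!is.finite(m)] <- 0
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}
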