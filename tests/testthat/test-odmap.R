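test_that("standardization is exact, affine-invariant, and guarded", {
  set.seed(4)
  m <- matrix(rnorm(9, 5, 2), 3, 3)
  z <- standardize_map(m)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, (m - mean(m)) / sd(m))      # direct-formula oracle
  # affine invariance: a*x + b standardizes to the same map
  expect_equal(standardize_map(3 * m + 7), z, tolerance = 1e-12)
  # already-standard input is unchanged
  expect_equal(standardize_map(z), z, tolerance = 1e-12)
  expect_error(standardize_map(matrix(5, 3, 3)), "zero variance")
  expect_error(standardize_map(m, region = matrix(FALSE, 3, 3)), "> 1")
})

test_that("OD maps are antisymmetric differences over the crop", {
  set.seed(6)
  a <- matrix(rnorm(30), 5, 6)
  b <- matrix(rnorm(30), 5, 6)
  expect_equal(od_map(a, a)$od_index, matrix(0, 5, 6))
  ab <- od_map(a, b); ba <- od_map(b, a)
  expect_equal(ab$od_index, -ba$od_index)
  crop <- matrix(FALSE, 5, 6); crop[2:4, 2:5] <- TRUE
  cm <- od_map(a, b, crop)
  expect_true(all(is.na(cm$od_index[!crop])))
  expect_equal(cm$od_index[crop], (a - b)[crop])
})

test_that("OD sign recovers the generator's column phase in layer IV", {
  fx <- od_session()
  od <- od_map_from_tensor(fx$tensor, crop = fx$cortex$mask)
  l4 <- fx$cortex$layer_index == "IV" & fx$cortex$mask
  agree <- mean(sign(od$od_index[l4]) == fx$cortex$od_phase[l4],
                na.rm = TRUE)
  expect_gt(agree, 0.9)
  # balanced design: OD index approximately centered over the crop
  expect_lt(abs(mean(od$od_index[fx$cortex$mask])), 0.2)
})

test_that("even/odd shuffling cancels the columnar signal", {
  fx <- od_session()
  sh <- shuffle_control(fx$tensor, crop = fx$cortex$mask)
  od <- od_map_from_tensor(fx$tensor, crop = fx$cortex$mask)
  expect_equal(sh$provenance, "shuffled")
  # the shuffled map carries far less columnar power in layer IV
  it <- spectral_index(layer_spectrum(layer_profile(od, fx$cortex, "IV")))
  is <- spectral_index(layer_spectrum(layer_profile(sh, fx$cortex, "IV")))
  expect_gt(it, is)
  # the true map correlates with the ground-truth phase; the shuffled
  # map essentially does not
  l4 <- fx$cortex$layer_index == "IV" & fx$cortex$mask
  expect_gt(cor(od$od_index[l4], fx$cortex$od_phase[l4]), 0.7)
  expect_lt(abs(cor(sh$od_index[l4], fx$cortex$od_phase[l4])), 0.4)
})

test_that("layer segmentation between parallel paths is a row gradient", {
  top <- cbind(c(0, 8.8), c(1, 1))
  bottom <- cbind(c(0, 8.8), c(3, 3))
  seg <- segment_layers(top, bottom, nz = 40, nx = 80)
  rows_in <- which(rowSums(seg$inside) > 0)
  z <- (rows_in - 0.5) * 0.1
  got <- vapply(rows_in, function(r) mean(seg$depth[r, seg$inside[r, ]]),
                numeric(1))
  expect_equal(got, (z - 1) / 2, tolerance = 0.02)
  # depth 0.5 falls in layer IV under the default fraction table
  mid <- which.min(abs(got - 0.5))
  expect_true(all(seg$layer[rows_in[mid], seg$inside[rows_in[mid], ]] == "IV"))
  expect_error(segment_layers(top, cbind(c(0, 8.8), c(3, 0.5)),
                              nz = 40, nx = 80), "crossing")
})

test_that("curved-path depths match a brute-force nearest-point oracle", {
  xs <- seq(0.3, 8.5, length.out = 40)
  top <- cbind(xs, 1.5 + 0.5 * sin(xs / 1.5))
  bottom <- cbind(xs, 3.2 + 0.5 * sin(xs / 1.5))
  seg <- segment_layers(top, bottom, nz = 50, nx = 80)
  # oracle: dense sampling of both paths, plain nearest-point distances
  dense <- function(p) {
    s <- seq(0, 1, length.out = 4000)
    cbind(approx(seq(0, 1, length.out = nrow(p)), p[, 1], s)$y,
          approx(seq(0, 1, length.out = nrow(p)), p[, 2], s)$y)
  }
  dt <- dense(top); db <- dense(bottom)
  idx <- which(seg$inside)[seq(1, sum(seg$inside), by = 29)]
  for (i in idx) {
    r <- ((i - 1) %% 50) + 1; c <- ((i - 1) %/% 50) + 1
    p <- c((c - 0.5) * 0.11, (r - 0.5) * 0.1)
    d1 <- sqrt(min((dt[, 1] - p[1])^2 + (dt[, 2] - p[2])^2))
    d2 <- sqrt(min((db[, 1] - p[1])^2 + (db[, 2] - p[2])^2))
    expect_lt(abs(seg$depth[i] - d1 / (d1 + d2)), 0.11)  # within 1 pixel
  }
})

test_that("layer profiles are centered, origin-anchored, and faithful", {
  cx <- small_cortex()
  # constant OD -> flat centered profile at zero
  od_c <- matrix(0.7, 30, 80)
  pr <- layer_profile(od_c, cx, "IV")
  expect_lt(max(abs(pr$od_raw)), 1e-9)
  expect_lt(max(abs(pr$od_fit)), 1e-6)
  expect_equal(pr$distance[1], 0)          # origin at the left edge
  expect_true(all(diff(pr$distance) == 100))
  # a 1000-um sinusoid survives 100-um resampling nearly unattenuated
  od_s <- matrix(NA_real_, 30, 80)
  od_s[cx$mask] <- sin(2 * pi * cx$arc_length[cx$mask] / 1000)
  prs <- layer_profile(od_s, cx, "IV")
  expect_gt(diff(range(prs$od_fit)) / 2, 0.98 * 1)
  expect_error(layer_profile(od_c, cx, "IV",
                             roi = matrix(FALSE, 30, 80)), "10 samples")
})

test_that("extrema detection enforces prominence and absolute value", {
  x <- seq(0, 5000, by = 100)
  prof <- make_profile(sin(2 * pi * x / 1000))
  ex <- find_extrema(prof)
  expect_equal(nrow(ex$maxima), 5)
  expect_equal(nrow(ex$minima), 5)
  expect_true(all(ex$maxima$value > 0.25))
  expect_true(all(ex$minima$value < -0.25))
  # amplitude 0.2 fails the absolute-value gate
  ex2 <- find_extrema(make_profile(0.2 * sin(2 * pi * x / 1000)))
  expect_equal(nrow(ex2$maxima), 0)
  expect_equal(nrow(ex2$minima), 0)
})

test_that("prominence matches an exhaustive scan on random profiles", {
  set.seed(12)
  y <- cumsum(rnorm(120)) / 3
  peaks <- which(diff(sign(diff(y))) < 0) + 1
  got <- fusmap:::peak_prominence(y, peaks)
  # oracle: brute-force definition, walking every peak's two sides
  oracle <- vapply(peaks, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    hig <- which(left > h)
    lmin <- min(left[if (length(hig)) (max(hig) + 1):(i - 1) else 1:(i - 1)])
    right <- y[(i + 1):length(y)]
    hig <- which(right > h)
    rmin <- min(right[seq_len(if (length(hig)) min(hig) - 1 else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("mean bandwidth is the pooled half-distance between extrema", {
  x <- seq(0, 6000, by = 100)
  ex <- find_extrema(make_profile(cos(2 * pi * x / 1000)))
  bw <- mean_bandwidth(ex)
  expect_equal(bw$mean_um, 500)
  expect_equal(bw$sem_um, 0)
  # two extrema only: single half-distance, flagged, SEM 0
  two <- list(maxima = tibble::tibble(index = c(1, 11),
                                      distance = c(0, 1040),
                                      value = c(1, 1),
                                      prominence = c(2, 2)),
              minima = tibble::tibble(index = integer(),
                                      distance = numeric(),
                                      value = numeric(),
                                      prominence = numeric()))
  bw2 <- mean_bandwidth(two)
  expect_equal(bw2$mean_um, 520)
  expect_true(bw2$single_interval)
  expect_equal(bw2$sem_um, 0)
  expect_error(mean_bandwidth(list(maxima = two$minima,
                                   minima = two$minima)),
               "insufficient")
})

test_that("layer spectra match a naive DFT and locate pure tones", {
  x <- seq(0, 22000 - 100, by = 100)
  y <- cos(2 * pi * x / 1100)
  sp <- layer_spectrum(make_profile(y))
  expect_equal(sp$frequency[which.max(sp$magnitude)], 1 / 1100,
               tolerance = 1 / (length(y) * 100))
  expect_equal(max(sp$magnitude), 1)
  # constant profile: all energy at zero frequency
  spc <- layer_spectrum(make_profile(rep(3, 64)))
  expect_equal(spc$magnitude[1], 1)
  expect_lt(max(spc$magnitude[-(1:2)]), 1e-9)
  # naive-DFT oracle (before smoothing/normalization)
  set.seed(2)
  y2 <- rnorm(40)
  n <- length(y2)
  raw <- vapply(0:(n %/% 2), function(k) {
    Mod(sum(y2 * exp(-2i * pi * k * (0:(n - 1)) / n)))
  }, numeric(1))
  sm <- vapply(seq_along(raw), function(i) {
    mean(raw[max(1, i - 1):min(length(raw), i + 1)])
  }, numeric(1))
  expect_equal(layer_spectrum(make_profile(y2))$magnitude,
               sm / max(sm), tolerance = 1e-8)
})

test_that("the spectral index integrates the OD band and is scale-free", {
  expect_equal(od_band(), c(1 / 1400, 1 / 700))
  x <- seq(0, 44000 - 100, by = 100)
  tone <- cos(2 * pi * x / 1100)       # in-band period
  sp <- layer_spectrum(make_profile(tone))
  expect_gt(spectral_index(sp), 0.8)
  expect_lt(spectral_index(layer_spectrum(make_profile(rep(5, 64)))), 0.05)
  # scaling invariance and range
  sp2 <- layer_spectrum(make_profile(25 * tone))
  expect_equal(spectral_index(sp2), spectral_index(sp), tolerance = 1e-12)
  expect_true(spectral_index(sp) >= 0 && spectral_index(sp) <= 1)
  expect_error(spectral_index(sp, band = c(1, 2)), "outside")
})

test_that("white-noise profiles carry the flat-spectrum band fraction", {
  set.seed(99)
  idx <- replicate(120, {
    spectral_index(layer_spectrum(make_profile(rnorm(200))))
  })
  nyq <- 1 / (2 * 100)
  expect_lt(abs(mean(idx) - diff(od_band()) / nyq), 0.03)
})

test_that("laminar selectivity table flags missing layers", {
  fx <- od_session()
  od <- od_map_from_tensor(fx$tensor, crop = fx$cortex$mask)
  tab <- layer_selectivity_table(od, fx$cortex)
  expect_equal(nrow(tab), 5)
  expect_true(all(is.finite(tab$spectral_index)))
  expect_true(all(tab$spectral_index >= 0 & tab$spectral_index <= 1))
  # an ROI that misses a layer yields a flagged (NA) cell
  roi <- fx$cortex$layer_index == "IV" & fx$cortex$mask
  tab2 <- layer_selectivity_table(od, fx$cortex, rois = list(l4 = roi))
  expect_true(is.na(tab2$spectral_index[tab2$layer == "I"]))
  expect_true(is.finite(tab2$spectral_index[tab2$layer == "IV"]))
})
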