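series_from_matrix <- function(M, nz, nx, dt = 1) {
  new_series(array(t(matrix(M, ncol = nz * nx, byrow = FALSE)),
                   c(nz, nx, ncol(M))), dt = dt)
}

test_that("cubic-spline upsampling preserves knots and cubics", {
  nz <- 2; nx <- 3; Tn <- 12
  tt <- seq_len(Tn)
  poly <- 0.5 + 0.3 * tt - 0.02 * tt^2 + 0.001 * tt^3
  M <- rbind(rep(4, Tn),                # constant
             poly,
             sin(tt / 3), cos(tt / 2), tt, sqrt(tt))
  dimnames(M) <- NULL
  s <- new_series(array(M, c(nz, nx, Tn)))
  out <- interpolate_temporal(s, 10)
  expect_equal(dim(out$images)[3], (Tn - 1) * 10 + 1)
  expect_equal(out$dt, 0.1)
  O <- matrix(out$images, nz * nx, dim(out$images)[3])
  knots <- seq(1, dim(out$images)[3], by = 10)
  expect_equal(O[, knots], M, tolerance = 1e-12)
  expect_equal(O[1, ], rep(4, ncol(O)), tolerance = 1e-12)
  # cubic reproduced exactly away from the boundary (oracle: direct
  # polynomial evaluation)
  tfine <- seq(1, Tn, by = 0.1)
  interior <- tfine >= 2 & tfine <= Tn - 1
  oracle <- 0.5 + 0.3 * tfine - 0.02 * tfine^2 + 0.001 * tfine^3
  expect_lt(max(abs(O[2, interior] - oracle[interior])), 1e-9)
  expect_error(interpolate_temporal(new_series(array(1, c(2, 2, 3))), 10),
               "at least 4")
})

test_that("3D smoothing has unit DC gain and the analytic noise shrinkage", {
  cst <- new_series(array(7, c(5, 6, 8)))
  expect_equal(smooth3d(cst)$images, cst$images, tolerance = 1e-12)
  # impulse response: the kernel itself, summing to 1
  imp <- array(0, c(7, 7, 7)); imp[4, 4, 4] <- 1
  k <- smooth3d(new_series(imp))$images
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_true(all(k[4 + (-1:1), 4 + (-1:1), 4 + (-1:1)] > 0))
  expect_equal(max(k), k[4, 4, 4])
  expect_equal(sum(k > 1e-15), 27)
  # white-noise variance reduced by the kernel's sum of squared weights
  set.seed(11)
  noise <- array(rnorm(60 * 60 * 40), c(60, 60, 40))
  sm <- smooth3d(new_series(noise))$images
  core <- sm[2:59, 2:59, 2:39]
  expect_equal(stats::var(as.vector(core)),
               fusmap:::smooth_kernel_ssq(0.65), tolerance = 0.05)
})

test_that("epoching normalizes to percent change over the baseline", {
  nz <- 2; nx <- 2; Tn <- 40
  ev <- tibble::tibble(trial_id = 1L, t_onset = 20, condition_id = 1L,
                       stimulus_kind = "eccentricity",
                       stim_duration = 0.5, correct = TRUE)
  class(ev) <- c("fus_event_log", class(ev))
  # flat series -> all-zero tensor
  s <- new_series(array(50, c(nz, nx, Tn)))
  tens <- epoch_and_normalize(interpolate_temporal(s, 10), ev)
  expect_equal(max(abs(tens$data)), 0, tolerance = 1e-9)
  # step to 1.2x baseline at onset -> +20% plateau
  M <- matrix(100, nz * nx, Tn)
  M[, 21:Tn] <- 120
  s2 <- new_series(array(rep(M[1, ], each = nz * nx), c(nz, nx, Tn)))
  tens2 <- epoch_and_normalize(interpolate_temporal(s2, 10), ev)
  plateau <- tens2$data[1, tens2$rel_time >= 2 & tens2$rel_time <= 8, 1]
  expect_equal(mean(plateau), 20, tolerance = 0.5)
  # baseline window mean is zero per pixel per trial
  expect_lt(max(abs(rowMeans(tens2$data[, tens2$rel_time >= -5 &
                                          tens2$rel_time < 0, 1]))), 1e-9)
})

test_that("trials without a full epoch are dropped with a warning", {
  nz <- 2; nx <- 2; Tn <- 30
  ev <- tibble::tibble(trial_id = 1:2, t_onset = c(2, 15),
                       condition_id = 1L, stimulus_kind = "eccentricity",
                       stim_duration = 0.5, correct = TRUE)
  class(ev) <- c("fus_event_log", class(ev))
  s <- interpolate_temporal(new_series(array(10, c(nz, nx, Tn))), 10)
  expect_warning(tens <- epoch_and_normalize(s, ev), "dropped")
  expect_equal(dim(tens$data)[3], 1)
  # incorrect trials are excluded; here the only correct trial also
  # lacks a full epoch, leaving an empty tensor
  ev$correct <- c(TRUE, FALSE)
  expect_warning(tens0 <- epoch_and_normalize(s, ev), "dropped")
  expect_equal(dim(tens0$data)[3], 0)
})

test_that("generator trial recovers its amplitude at the 2.5-s peak", {
  fx <- noiseless_tensor()
  tens <- fx$tensor
  px_img <- which.min(abs(fx$cortex$ecc_pref -
                            attr(fx$events, "stimuli")$value))
  px <- match(px_img, tens$pixel_index)
  tc <- rowMeans(tens$data[px, , ])
  expect_equal(max(tc), 16, tolerance = 1)
  expect_equal(tens$rel_time[which.max(tc)], 2.5, tolerance = 0.2)
  # baseline-zero invariant on real pipeline output
  bidx <- tens$rel_time >= -5 & tens$rel_time < 0
  expect_lt(max(abs(apply(tens$data[, bidx, , drop = FALSE],
                          c(1, 3), mean))), 1e-9)
})

test_that("windowed response means behave like time averages", {
  rel <- seq(-5, 10, by = 0.1)
  arr <- array(0, c(2, length(rel), 1))
  arr[1, , 1] <- 10
  win <- rel >= 2 & rel <= 3
  ramp <- rep(0, length(rel))
  ramp[win] <- seq(0, 10, length.out = sum(win))
  arr[2, , 1] <- ramp
  tens <- structure(list(data = arr, rel_time = rel,
                         pixel_index = 1:2, dim = c(2, 1),
                         condition_id = 1L, trial_id = 1L, t_onset = 30,
                         params = preproc_params(), meta = list()),
                    class = "fus_trial_tensor")
  rm <- response_mean(tens, c(2, 3))
  expect_equal(rm[1, 1], 10)
  expect_equal(rm[2, 1], 5, tolerance = 0.2)
})

test_that("windowed mean matches a rectangle rule on the raw 1-Hz samples", {
  fx <- noiseless_tensor()
  cx <- fx$cortex
  ev <- fx$events
  s_raw <- simulate_cbv_series(cx, ev, fx$hemo, noise_sd = 0, seed = 7)
  tens <- fx$tensor
  px_img <- which.min(abs(cx$ecc_pref - attr(ev, "stimuli")$value))
  px <- match(px_img, tens$pixel_index)
  got <- mean(response_mean(tens, c(2, 3))[px, ])
  # oracle: rectangle rule on the raw 1-Hz samples at t = 2, 3 s
  M <- matrix(s_raw$images, prod(cx$dim), dim(s_raw$images)[3])[px_img, ]
  times <- series_times(s_raw)
  oracle <- mean(vapply(ev$t_onset, function(on) {
    base <- mean(M[times >= on - 5 & times < on])
    mean(100 * (M[times %in% (round(on) + 2:3)] - base) / base)
  }, numeric(1)))
  expect_equal(got, oracle, tolerance = 0.5)
})

test_that("smoothing order barely matters on smooth noiseless data", {
  # regression: smoothing the whole series vs smoothing each trial's
  # epoch individually changes windowed responses by well under 1% of
  # the peak response on noiseless data
  fx <- noiseless_tensor()
  cx <- fx$cortex; ev <- fx$events
  s <- simulate_cbv_series(cx, ev, fx$hemo, noise_sd = 0, seed = 7)
  si <- interpolate_temporal(s, 10)
  a <- epoch_and_normalize(smooth3d(si), ev)
  ra <- response_mean(a, "fig1")
  # permuted order: epoch first (on the unsmoothed series), then smooth
  # each trial's epoch as its own short series
  params <- preproc_params()
  rel <- seq(params$epoch[1], params$epoch[2], by = si$dt)
  rb <- matrix(NA_real_, prod(cx$dim), nrow(ev))
  for (i in seq_len(nrow(ev))) {
    j <- round((ev$t_onset[i] + rel - si$t0) / si$dt) + 1
    sub <- new_series(si$images[, , j], dt = si$dt,
                      t0 = ev$t_onset[i] + rel[1])
    sub <- smooth3d(sub)
    ev1 <- ev[i, , drop = FALSE]
    tens1 <- epoch_and_normalize(sub, ev1)
    rb[, i] <- response_mean(tens1, "fig1")[, 1]
  }
  expect_lt(max(abs(ra - rb)) / max(ra), 0.01)
})
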