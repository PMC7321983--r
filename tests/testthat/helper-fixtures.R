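# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# A small straight-ribbon scene for fast pipeline-level tests: 30 x 80
# pixels, straight midline, 1.4-mm-thick ribbon.
small_cortex <- function(od_column_width = 500, ...) {
  make_cortex(nz = 30, nx = 80,
              path = cbind(seq(0.6, 80 * 0.11 - 0.6, length.out = 30),
                           1.5),
              thickness_mm = 1.4,
              od_column_width = od_column_width, ...)
}

# Noiseless single-condition session on the small scene, preprocessed.
noiseless_tensor <- function() {
  cached("noiseless_tensor", {
    cx <- small_cortex()
    stim <- stimulus_set("eccentricity")[5, ]
    attr(stim, "kind") <- "eccentricity"
    ev <- make_event_log(stim, 3, seed = 7)
    hemo <- hemodynamic_model(response_amplitude = 16)
    s <- simulate_cbv_series(cx, ev, hemo, noise_sd = 0, seed = 7)
    list(cortex = cx, events = ev, hemo = hemo,
         tensor = preprocess_series(s, ev))
  })
}

# OD session on the small scene with modest noise, preprocessed.
od_session <- function() {
  cached("od_session", {
    cx <- small_cortex(od_column_width = 520)
    ev <- make_event_log(stimulus_set("od"), 8, seed = 21)
    s <- simulate_cbv_series(cx, ev, noise_sd = 4, seed = 21)
    list(cortex = cx, events = ev,
         tensor = preprocess_series(s, ev))
  })
}

# Synthetic trial tensor built directly at the response level: every
# sample of each trial holds its (possibly noisy) response value, with
# a zero baseline. Used to test analysis operations in isolation.
response_tensor <- function(resp, rel_time = seq(-5, 10, by = 0.5),
                            dim = c(NA, NA), condition_id = NULL) {
  npix <- nrow(resp); ntr <- ncol(resp)
  if (anyNA(dim)) dim <- c(npix, 1)
  arr <- array(0, c(npix, length(rel_time), ntr))
  post <- rel_time >= 0
  for (k in seq_len(ntr)) arr[, post, k] <- resp[, k]
  structure(list(data = arr, rel_time = rel_time,
                 pixel_index = seq_len(npix), dim = dim,
                 condition_id = condition_id %||% rep(1L, ntr),
                 trial_id = seq_len(ntr),
                 t_onset = seq_len(ntr) * 10,
                 params = preproc_params(),
                 meta = list()),
            class = "fus_trial_tensor")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Uniform-pitch profile tibble for spectrum tests.
make_profile <- function(y, pitch = 100) {
  out <- tibble::tibble(distance = (seq_along(y) - 1) * pitch,
                        od_raw = y, od_fit = y)
  attr(out, "pitch_um") <- pitch
  attr(out, "layer") <- "IV"
  class(out) <- c("fus_layer_profile", class(out))
  out
}
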