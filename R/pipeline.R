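default_run_config <- function(protocol) {
  list(
    protocol = protocol,
    seed = 1,
    cortex = list(),                       # overrides for make_cortex()
    hemo = list(),                         # overrides for hemodynamic_model()
    noise_sd = 15,
    n_trials = switch(protocol,
                      fig1_reliability = 40,
                      eccentricity = 8, angular = 8, od = 20),
    stim_duration = 0.5,
    r2_threshold = 0.02,
    binarize_threshold = 10,
    pitch_um = 100,
    out_dir = NULL
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Run a full mapping pipeline
#'
#' Orchestrates generator, preprocessing and analysis for one protocol:
#' `"fig1_reliability"` (single-condition session, reliability curve,
#' Naka-Rushton fit, map SNR), `"eccentricity"` / `"angular"`
#' (retinotopic preference maps with split-half repeatability), or
#' `"od"` (ocular-dominance map, shuffle control, laminar bandwidth and
#' spectral-index table). Deterministic for a fixed seed; every derived
#' number is returned in a report tagged with its pipeline stage and the
#' configuration hash.
#'
#' @param config Named list of overrides (see `default_run_config`
#'   fields: `protocol`, `seed`, `n_trials`, `noise_sd`, `cortex`,
#'   `hemo`, thresholds, `out_dir`), or a path to a YAML file with the
#'   same structure. `protocol` is required.
#' @return A run report (list). If `out_dir` is set, the report is also
#'   written as JSON along with CSV/TIFF artifacts.
#' @export
run_pipeline <- function(config = list(protocol = "eccentricity")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(!is.null(config$protocol))
  cfg <- merge_config(default_run_config(config$protocol), config)
  cortex <- do.call(make_cortex, cfg$cortex)
  hemo <- do.call(hemodynamic_model, cfg$hemo)
  report <- list(protocol = cfg$protocol, seed = cfg$seed,
                 config_hash = rlang::hash(cfg))

  if (cfg$protocol == "fig1_reliability") {
    stim <- stimulus_set("eccentricity")
    stim <- stim[5, , drop = FALSE]        # one mid-eccentricity condition
    attr(stim, "kind") <- "eccentricity"
    events <- make_event_log(stim, cfg$n_trials,
                             stim_duration = cfg$stim_duration,
                             seed = cfg$seed)
    series <- simulate_cbv_series(cortex, events, hemo,
                                  noise_sd = cfg$noise_sd,
                                  seed = cfg$seed + 1)
    tensor <- preprocess_series(series, events)
    curve <- classification_analysis(tensor, window = "fig1",
                                     threshold = cfg$binarize_threshold,
                                     seed = cfg$seed + 2)
    fit <- fit_naka_rushton(curve)
    map10 <- activation_map(tensor, trials = 1:10, window = "fig1")
    quiet <- !cortex$mask & is.finite(map10$values)
    report$stages <- list(
      reliability = list(curve = curve[, 1:3], naka_rushton = tidy(fit)),
      snr = list(snr_db_10_trials = snr_db(map10, cortex$mask, quiet),
                 p_correct_n20 = curve$proportion_correct[20])
    )
    artifacts <- list(curve = curve, fit = fit, map = map10)
  } else if (cfg$protocol %in% c("eccentricity", "angular")) {
    stim <- stimulus_set(cfg$protocol)
    events <- make_event_log(stim, cfg$n_trials,
                             stim_duration = cfg$stim_duration,
                             seed = cfg$seed)
    series <- simulate_cbv_series(cortex, events, hemo,
                                  noise_sd = cfg$noise_sd,
                                  seed = cfg$seed + 1)
    tensor <- preprocess_series(series, events)
    half_maps <- function(parity) {
      lapply(stim$condition_id, function(cid) {
        idx <- which(tensor$condition_id == cid)
        idx <- idx[seq_along(idx) %% 2 == parity]
        activation_map(tensor, trials = idx, window = "retinotopy")
      })
    }
    maps <- lapply(stim$condition_id, function(cid)
      activation_map(tensor, condition = cid, window = "retinotopy"))
    pm <- postprocess_map(preference_map(
      condition_stack(maps, stimuli = stim),
      r2_threshold = cfg$r2_threshold, mask = cortex$mask))
    pm_a <- preference_map(condition_stack(half_maps(0), stimuli = stim),
                           r2_threshold = cfg$r2_threshold,
                           mask = cortex$mask)
    pm_b <- preference_map(condition_stack(half_maps(1), stimuli = stim),
                           r2_threshold = cfg$r2_threshold,
                           mask = cortex$mask)
    report$stages <- list(
      preference_map = list(n_valid = sum(pm$valid)),
      repeatability = list(pct_within_2 = repeatability(pm_a, pm_b, 2))
    )
    artifacts <- list(pm = pm)
  } else if (cfg$protocol == "od") {
    stim <- stimulus_set("od")
    events <- make_event_log(stim, cfg$n_trials,
                             stim_duration = cfg$stim_duration,
                             seed = cfg$seed)
    series <- simulate_cbv_series(cortex, events, hemo,
                                  noise_sd = cfg$noise_sd,
                                  seed = cfg$seed + 1)
    tensor <- preprocess_series(series, events)
    od <- od_map_from_tensor(tensor, crop = cortex$mask)
    shuf <- shuffle_control(tensor, crop = cortex$mask)
    prof <- layer_profile(od, cortex, layer = "IV",
                          pitch_um = cfg$pitch_um)
    ext <- find_extrema(prof)
    bw <- tryCatch(mean_bandwidth(ext), error = function(e) NULL)
    tab <- layer_selectivity_table(od, cortex, pitch_um = cfg$pitch_um)
    tab_s <- layer_selectivity_table(shuf, cortex, pitch_um = cfg$pitch_um)
    report$stages <- list(
      od = list(bandwidth_um = bw$mean_um, bandwidth_sem_um = bw$sem_um,
                selectivity = tab,
                shuffled_selectivity = tab_s)
    )
    artifacts <- list(od = od, shuffled = shuf, profile = prof,
                      extrema = ext)
  } else {
    stop("unknown protocol: ", cfg$protocol)
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report,
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(artifacts$curve)) {
      readr::write_csv(as.data.frame(artifacts$curve),
                       file.path(cfg$out_dir, "reliability.csv"))
    }
    if (!is.null(artifacts$od) &&
        requireNamespace("tiff", quietly = TRUE)) {
      write_map_tiff(artifacts$od$od_index,
                     file.path(cfg$out_dir, "od_map.tif"))
    }
    if (!is.null(artifacts$pm) &&
        requireNamespace("tiff", quietly = TRUE)) {
      write_map_tiff(list(artifacts$pm$center, artifacts$pm$width),
                     file.path(cfg$out_dir, "preference_map.tif"))
    }
  }
  report$artifacts <- artifacts
  invisible(report)
}
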