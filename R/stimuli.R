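#' Stimulus condition sets
#'
#' Builds the table of visual conditions used by the mapping protocols:
#' 9 hemiconcentric eccentricity bands of 1.5 degrees of visual angle (DVA)
#' covering 1.5--15 DVA, 12 polar-angle wedges of 15 degrees covering the
#' left hemifield (0--180 degrees), or the two monocular full-field
#' conditions used for ocular-dominance mapping.
#'
#' @param kind One of `"eccentricity"`, `"angular"`, `"od"`.
#' @param ecc_range Stimulated eccentricity range in DVA (eccentricity
#'   protocol only).
#' @param band_width Condition width: 1.5 DVA (eccentricity) or 15 degrees
#'   (angular). Ignored for `"od"`.
#' @return A tibble with one row per condition: `condition_id`, `value`
#'   (band/wedge centre in DVA or degrees; +1/-1 eye sign for OD),
#'   `stimulus_kind`, and `eye` (`"contra"`, `"ipsi"` or `NA`).
#' @examples
#' stimulus_set("eccentricity")
#' stimulus_set("od")
#' @export
stimulus_set <- function(kind = c("eccentricity", "angular", "od"),
                         ecc_range = c(1.5, 15),
                         band_width = NULL) {
  kind <- match.arg(kind)
  if (kind == "eccentricity") {
    bw <- band_width %||% 1.5
    n <- round(diff(ecc_range) / bw)
    centers <- ecc_range[1] + bw * (seq_len(n) - 0.5)
    out <- tibble::tibble(
      condition_id = seq_len(n),
      value = centers,
      stimulus_kind = "eccentricity",
      eye = NA_character_
    )
  } else if (kind == "angular") {
    bw <- band_width %||% 15
    n <- round(180 / bw)
    centers <- bw * (seq_len(n) - 0.5)
    out <- tibble::tibble(
      condition_id = seq_len(n),
      value = centers,
      stimulus_kind = "angular",
      eye = NA_character_
    )
  } else {
    out <- tibble::tibble(
      condition_id = 1:2,
      value = c(1, -1),
      stimulus_kind = c("od_contra", "od_ipsi"),
      eye = c("contra", "ipsi")
    )
  }
  attr(out, "kind") <- kind
  class(out) <- c("fus_stimulus_set", class(out))
  out
}

#' Simulate a behavioural session event log
#'
#' Generates the trial sequence of a passive-fixation session: conditions
#' randomly interleaved with exact per-condition counts, a 500-ms central
#' fixation preceding each stimulus, and an intertrial interval of at
#' least 3 s. Onset times are stimulus onsets in seconds from session
#' start.
#'
#' @param stimuli A [stimulus_set()].
#' @param n_trials_per_condition Trials per condition (>= 1).
#' @param n_blank Number of interleaved blank (control) trials with no
#'   peripheral stimulus (`condition_id` 0).
#' @param stim_duration Stimulus duration in seconds (0.5 or 2 in the
#'   protocols modelled here).
#' @param fixation_s Pre-stimulus fixation duration (s).
#' @param iti_s Intertrial interval (s); must be >= 3.
#' @param lead_in_s Time before the first fixation (s); keep >= 5 so the
#'   first trial has a full baseline window.
#' @param jitter_s Upper bound of the uniform onset jitter added to each
#'   intertrial gap (s).
#' @param p_correct Probability a trial is a correct fixation.
#' @param seed Integer seed; identical seeds give identical logs.
#' @return A tibble of class `fus_event_log` with columns `trial_id`,
#'   `t_onset`, `condition_id`, `stimulus_kind`, `stim_duration`,
#'   `correct`.
#' @export
make_event_log <- function(stimuli, n_trials_per_condition,
                           n_blank = 0,
                           stim_duration = 0.5,
                           fixation_s = 0.5, iti_s = 3,
                           lead_in_s = 6, jitter_s = 0,
                           p_correct = 1, seed = 1) {
  stopifnot(n_trials_per_condition >= 1, iti_s >= 3, fixation_s >= 0)
  withr_seed(seed)
  ids <- c(rep(stimuli$condition_id, each = n_trials_per_condition),
           rep(0L, n_blank))
  order <- sample.int(length(ids))
  ids <- ids[order]
  n <- length(ids)
  gaps <- fixation_s + stim_duration + iti_s +
    stats::runif(n, 0, jitter_s)
  onset <- lead_in_s + fixation_s + c(0, cumsum(gaps[-n]))
  kind_of <- c("0" = "blank",
               stats::setNames(stimuli$stimulus_kind,
                               as.character(stimuli$condition_id)))
  out <- tibble::tibble(
    trial_id = seq_len(n),
    t_onset = onset,
    condition_id = as.integer(ids),
    stimulus_kind = unname(kind_of[as.character(ids)]),
    stim_duration = stim_duration,
    correct = stats::runif(n) <= p_correct
  )
  attr(out, "stimuli") <- stimuli
  attr(out, "timing") <- list(fixation_s = fixation_s, iti_s = iti_s,
                              lead_in_s = lead_in_s, jitter_s = jitter_s)
  class(out) <- c("fus_event_log", class(out))
  out
}

#' Read / write event logs as CSV
#'
#' @param x An event log tibble.
#' @param path File path.
#' @return `read_event_log()` returns a `fus_event_log` tibble.
#' @export
write_event_log <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           trial_id = "i", t_onset = "d",
                           condition_id = "i", stimulus_kind = "c",
                           stim_duration = "d", correct = "l"))
  if (is.unsorted(out$t_onset, strictly = TRUE)) {
    stop("event log onsets must be strictly increasing")
  }
  class(out) <- c("fus_event_log", class(out))
  out
}

#' Session acquisition time budget
#'
#' Total stimulation-driven acquisition time for a perfect session:
#' `n_conditions * n_trials * (fixation_s + post_onset_s)` seconds. With
#' the polar-angle protocol (12 conditions, 10 trials, 0.5-s fixation and
#' 3 s of post-onset acquisition) this is 420 s.
#'
#' @param n_conditions,n_trials Positive integers.
#' @param fixation_s,post_onset_s Per-trial fixation and post-onset
#'   acquisition durations (s).
#' @return Seconds (numeric scalar).
#' @examples
#' session_time_budget(12, 10, 0.5, 3) # 420
#' @export
session_time_budget <- function(n_conditions, n_trials,
                                fixation_s, post_onset_s) {
  stopifnot(n_conditions > 0, n_trials > 0,
            fixation_s >= 0, post_onset_s > 0)
  n_conditions * n_trials * (fixation_s + post_onset_s)
}
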