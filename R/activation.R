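new_activation_map <- function(values, n_trials, condition_id, window) {
  structure(list(values = values, n_trials = n_trials,
                 condition_id = condition_id, window = window),
            class = "fus_activation_map")
}

#' @export
print.fus_activation_map <- function(x, ...) {
  cat("<fus_activation_map> ", nrow(x$values), "x", ncol(x$values),
      "; ", x$n_trials, " trial(s), window ",
      paste(x$window, collapse = ".."), " s\n", sep = "")
  invisible(x)
}

# Rebuild a full image from per-pixel values at tensor$pixel_index.
tensor_image <- function(tensor, v) {
  img <- matrix(NA_real_, tensor$dim[1], tensor$dim[2])
  img[tensor$pixel_index] <- v
  img
}

#' Trial-averaged activation map
#'
#' Per-pixel mean of the windowed response over a subset of trials, in
#' percent CBV change.
#'
#' @param tensor A `fus_trial_tensor`.
#' @param trials Trial indices into the tensor (default: all trials of
#'   `condition`, or all trials).
#' @param condition Optional condition id filter.
#' @param window Response window (see [response_mean()]).
#' @return A `fus_activation_map` whose `$values` is a full `nz x nx`
#'   image (`NA` at pixels absent from the tensor).
#' @export
activation_map <- function(tensor, trials = NULL, condition = NULL,
                           window = "fig1") {
  idx <- seq_along(tensor$condition_id)
  if (!is.null(condition)) idx <- idx[tensor$condition_id[idx] %in% condition]
  if (!is.null(trials)) idx <- trials
  if (!length(idx)) stop("empty trial subset")
  resp <- response_mean(tensor, window)
  v <- rowMeans(resp[, idx, drop = FALSE])
  new_activation_map(tensor_image(tensor, v), length(idx),
                     condition_id = unique(tensor$condition_id[idx]),
                     window = attr(resp, "window"))
}

#' Binarize an activation map
#'
#' @param map A `fus_activation_map` (or numeric matrix).
#' @param threshold Percent-CBV threshold; a pixel is active iff its
#'   value is `>= threshold`. `NA` pixels are inactive.
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold = 10) {
  v <- if (inherits(map, "fus_activation_map")) map$values else map
  out <- !is.na(v) & v >= threshold
  out
}

#' Trial-count reliability (correct-classification) analysis
#'
#' For each session of at least 40 trials of one condition (sessions
#' with more are split into notional 40-trial sessions): draw 20 trials
#' at random for a reference activation map, binarize it at a 10%
#' CBV increase, and for each number of averaged trials n = 1..20 draw
#' 100 random combinations from the remaining trials, binarize each
#' combination's map at the same threshold, and score the fraction of
#' pixels classified identically to the reference (true positives plus
#' true negatives over all pixels). Returns the combination mean per n
#' per session and the grand mean across sessions.
#'
#' @param tensor A `fus_trial_tensor`.
#' @param condition Condition id to analyse (default: the most frequent).
#' @param window Response window (default the 2--3-s reliability window).
#' @param threshold Binarization threshold (% CBV).
#' @param n_ref Reference-map trial count.
#' @param n_max Largest number of averaged trials.
#' @param n_combos Random combinations per n.
#' @param seed Integer seed for the trial draws.
#' @return A tibble of class `fus_reliability`: columns `n_averaged`,
#'   `proportion_correct` (grand mean), `sd_sessions`, plus one
#'   `session_<i>` column per notional session.
#' @export
classification_analysis <- function(tensor, condition = NULL,
                                    window = "fig1", threshold = 10,
                                    n_ref = 20, n_max = 20,
                                    n_combos = 100, seed = 1) {
  cid <- tensor$condition_id
  condition <- condition %||%
    as.integer(names(sort(table(cid), decreasing = TRUE))[1])
  idx <- which(cid == condition)
  per_session <- n_ref + n_max
  if (length(idx) < per_session) {
    warning("session skipped: fewer than ", per_session,
            " trials of condition ", condition)
    return(NULL)
  }
  withr_seed(seed)
  resp <- response_mean(tensor, window)[, idx, drop = FALSE]
  n_sessions <- length(idx) %/% per_session
  sess_curves <- matrix(NA_real_, n_max, n_sessions)
  for (s in seq_len(n_sessions)) {
    block <- resp[, (s - 1) * per_session + seq_len(per_session),
                  drop = FALSE]
    ref_trials <- sample.int(per_session, n_ref)
    ref_bin <- rowMeans(block[, ref_trials, drop = FALSE]) >= threshold
    pool <- setdiff(seq_len(per_session), ref_trials)
    for (n in seq_len(n_max)) {
      props <- numeric(n_combos)
      for (k in seq_len(n_combos)) {
        comb <- sample(pool, n)
        bin <- rowMeans(block[, comb, drop = FALSE]) >= threshold
        props[k] <- mean(bin == ref_bin)
      }
      sess_curves[n, s] <- mean(props)
    }
  }
  out <- tibble::tibble(
    n_averaged = seq_len(n_max),
    proportion_correct = rowMeans(sess_curves),
    sd_sessions = apply(sess_curves, 1, stats::sd)
  )
  for (s in seq_len(n_sessions)) out[[paste0("session_", s)]] <- sess_curves[, s]
  attr(out, "condition") <- condition
  attr(out, "threshold") <- threshold
  class(out) <- c("fus_reliability", class(out))
  out
}

#' Naka-Rushton fit of a reliability curve
#'
#' Least-squares fit of
#' `p(n) = baseline + r_max * n^e / (n^e + n50^e)` by a deterministic
#' multi-start grid over `(n50, e)` (baseline and `r_max` are linear
#' given the shape and solved exactly per grid point), refined by
#' Nelder-Mead on `(log n50, log e)`.
#'
#' @param curve A `fus_reliability` tibble, or a data frame with columns
#'   `n_averaged` and `proportion_correct`.
#' @return Object of class `fus_naka_rushton` with elements `r_max`,
#'   `n_50`, `exponent`, `baseline`, `rss`, `fitted`, `converged`.
#' @export
fit_naka_rushton <- function(curve) {
  n <- curve$n_averaged
  p <- curve$proportion_correct
  if (length(unique(n)) < 4) stop("need >= 4 distinct n values")

  solve_linear <- function(n50, e) {
    g <- n^e / (n^e + n50^e)
    X <- cbind(1, g)
    fit <- stats::lm.fit(X, p)
    list(baseline = fit$coefficients[1], r_max = fit$coefficients[2],
         rss = sum(fit$residuals^2))
  }
  grid <- expand.grid(n50 = c(0.5, 1, 2, 3, 5, 8, 12, 20),
                      e = c(0.5, 1, 1.5, 2, 3, 4))
  rss <- mapply(function(a, b) solve_linear(a, b)$rss, grid$n50, grid$e)
  best <- grid[which.min(rss), ]
  obj <- function(th) solve_linear(exp(th[1]), exp(th[2]))$rss
  opt <- stats::optim(log(c(best$n50, best$e)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  n50 <- exp(opt$par[1]); e <- exp(opt$par[2])
  lin <- solve_linear(n50, e)
  structure(list(
    r_max = unname(lin$r_max), n_50 = n50, exponent = e,
    baseline = unname(lin$baseline), rss = lin$rss,
    fitted = lin$baseline + lin$r_max * n^e / (n^e + n50^e),
    n_averaged = n, data = p,
    converged = opt$convergence == 0
  ), class = "fus_naka_rushton")
}

#' Predict from a Naka-Rushton fit
#' @param object A `fus_naka_rushton` fit.
#' @param newdata Optional vector of trial counts.
#' @param ... Unused.
#' @return Fitted proportions.
#' @export
predict.fus_naka_rushton <- function(object, newdata = NULL, ...) {
  n <- newdata %||% object$n_averaged
  object$baseline + object$r_max * n^object$exponent /
    (n^object$exponent + object$n_50^object$exponent)
}

#' @export
print.fus_naka_rushton <- function(x, ...) {
  cat("<fus_naka_rushton> baseline ", signif(x$baseline, 4),
      ", r_max ", signif(x$r_max, 4), ", n50 ", signif(x$n_50, 4),
      ", exponent ", signif(x$exponent, 4),
      ", rss ", signif(x$rss, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a Naka-Rushton fit
#' @param x A `fus_naka_rushton`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.fus_naka_rushton <- function(x, ...) {
  tibble::tibble(term = c("baseline", "r_max", "n_50", "exponent"),
                 estimate = c(x$baseline, x$r_max, x$n_50, x$exponent))
}

#' Glance at a Naka-Rushton fit
#' @param x A `fus_naka_rushton`.
#' @param ... Unused.
#' @return One-row tibble with `rss`, `r.squared`, `nobs`, `converged`.
#' @exportS3Method generics::glance
glance.fus_naka_rushton <- function(x, ...) {
  tss <- sum((x$data - mean(x$data))^2)
  tibble::tibble(rss = x$rss,
                 r.squared = if (tss > 0) 1 - x$rss / tss else NA_real_,
                 nobs = length(x$data), converged = x$converged)
}

#' Activation-map signal-to-noise ratio in decibels
#'
#' `10 * log10(mean response in the active ROI / SD of the quiet ROI)`.
#' Experimental reports quote map SNRs in dB without a formula; this
#' definition is the package's convention.
#'
#' @param map A `fus_activation_map` or numeric matrix.
#' @param active_roi,quiet_roi Disjoint logical masks.
#' @return SNR in dB.
#' @export
snr_db <- function(map, active_roi, quiet_roi) {
  v <- if (inherits(map, "fus_activation_map")) map$values else map
  if (any(active_roi & quiet_roi)) stop("ROIs must be disjoint")
  s <- stats::sd(v[quiet_roi])
  if (!is.finite(s) || s == 0) stop("zero quiet-ROI SD")
  10 * log10(mean(v[active_roi]) / s)
}
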