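#' Peak Fz during the first 100 s after stimulus introduction
#'
#' @param fz An `fz_trace`.
#' @param intro_time Stimulus introduction time, s (must fall inside the
#'   trace).
#' @param window Window length after introduction, s (default 100).
#' @return Maximum Fz over `[intro_time, intro_time + window)`. If the
#'   window runs past the end of the trace it is truncated and the result
#'   carries attribute `truncated = TRUE`.
#' @export
introduction_peak <- function(fz, intro_time, window = 100) {
  fz <- as_fz(fz)
  if (intro_time < fz$time[1L] || intro_time > fz$time[length(fz$time)]) {
    stop("`intro_time` lies outside the trace")
  }
  idx <- which(fz$time >= intro_time & fz$time < intro_time + window)
  if (!length(idx)) stop("empty introduction window")
  out <- max(fz$fz[idx])
  if (intro_time + window > fz$time[length(fz$time)] + 1e-9) {
    attr(out, "truncated") <- TRUE
  }
  out
}

#' Mean of per-presentation peak Fz
#'
#' For head-fixed sessions: the maximum Fz within each stimulus presentation,
#' averaged over presentations.
#'
#' @param fz An `fz_trace`.
#' @param presentations A [bout_table()] (or data frame) of presentation
#'   intervals; all rows are used.
#' @return Mean over presentations of the within-presentation maximum Fz.
#' @export
presentation_peak <- function(fz, presentations) {
  fz <- as_fz(fz)
  pres <- as.data.frame(presentations)
  if (!nrow(pres)) stop("no presentations supplied")
  peaks <- vapply(seq_len(nrow(pres)), function(i) {
    idx <- which(fz$time >= pres$onset_s[i] & fz$time < pres$offset_s[i])
    if (!length(idx)) return(NA_real_)
    max(fz$fz[idx])
  }, numeric(1L))
  mean(peaks, na.rm = TRUE)
}

#' Bout-weighted mean Fz during a behavior
#'
#' Averages Fz within each bout of the requested behavior, then averages
#' across bouts (each bout contributes equally, regardless of duration).
#'
#' @param fz An `fz_trace`.
#' @param bouts A [bout_table()].
#' @param label Behavior label.
#' @param stimulus Optional stimulus filter.
#' @return Mean across bouts of the within-bout mean Fz; `NA` when no bouts
#'   match.
#' @export
behavior_mean_fz <- function(fz, bouts, label = "investigation",
                             stimulus = NULL) {
  fz <- as_fz(fz)
  bt <- as.data.frame(bouts)
  sel <- bt$behavior == label
  if (!is.null(stimulus)) sel <- sel & bt$stimulus == stimulus
  bt <- bt[sel, , drop = FALSE]
  if (!nrow(bt)) return(NA_real_)
  means <- vapply(seq_len(nrow(bt)), function(i) {
    idx <- which(fz$time >= bt$onset_s[i] & fz$time < bt$offset_s[i])
    if (!length(idx)) return(NA_real_)
    mean(fz$fz[idx])
  }, numeric(1L))
  mean(means, na.rm = TRUE)
}

#' Mean Fz over a session window
#'
#' Average Fz over the whole period a stimulus/intruder is present.
#'
#' @param fz An `fz_trace`.
#' @param window Length-2 numeric `c(start, end)` in seconds.
#' @return Mean Fz over the window.
#' @export
session_mean_fz <- function(fz, window) {
  fz <- as_fz(fz)
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  idx <- which(fz$time >= window[1L] & fz$time < window[2L])
  if (!length(idx)) stop("the session window contains no samples")
  mean(fz$fz[idx])
}

#' Per-trial response detection, latency and session summaries
#'
#' For each bout of the requested behavior the Fz trace is normalized by
#' subtracting the signal at time 0 (the mean of the two samples straddling
#' the bout onset); the bout responds when this normalized response reaches
#' the threshold (default Z >= 1) before the bout offset, and the latency to
#' respond is the time from onset to the first threshold crossing.
#'
#' @param fz An `fz_trace`.
#' @param bouts A (merged) [bout_table()].
#' @param label Behavior label (default `"investigation"`).
#' @param stimulus Optional stimulus filter.
#' @param threshold Response threshold in normalized Fz units (default 1).
#' @return An object of class `trial_response_set`: data frame `trials`
#'   (onset, offset, duration, peak of the normalized response, responded,
#'   latency_s — `NA` unless responded), and summaries `percent_responsive`
#'   (pooled over bouts, 0-100), `mean_latency_s` (among responsive trials),
#'   `mean_bout_duration_s`, `n_trials`, `n_skipped` (bouts shorter than one
#'   sample, dropped with a warning), `threshold`.
#' @export
trial_responses <- function(fz, bouts, label = "investigation",
                            stimulus = NULL, threshold = 1) {
  fz <- as_fz(fz)
  bt <- as.data.frame(bouts)
  sel <- bt$behavior == label
  if (!is.null(stimulus)) sel <- sel & bt$stimulus == stimulus
  bt <- bt[sel, , drop = FALSE]
  time <- fz$time
  n <- length(time)

  rows <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(bt))) {
    idx <- which(time >= bt$onset_s[i] - 1e-9 & time < bt$offset_s[i] - 1e-9)
    if (bt$offset_s[i] - bt$onset_s[i] < 1 / fz$fs || length(idx) < 1L) {
      n_skipped <- n_skipped + 1L
      next
    }
    i0 <- max(findInterval(bt$onset_s[i] + 1e-9, time), 1L)
    f0 <- mean(fz$fz[c(i0, min(i0 + 1L, n))])
    nrm <- fz$fz[idx] - f0
    hit <- which(nrm >= threshold)
    responded <- length(hit) > 0L
    rows[[length(rows) + 1L]] <- data.frame(
      onset_s = bt$onset_s[i], offset_s = bt$offset_s[i],
      duration_s = bt$offset_s[i] - bt$onset_s[i],
      peak = max(nrm), responded = responded,
      latency_s = if (responded) time[idx[hit[1L]]] - bt$onset_s[i] else NA_real_)
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d bout(s) shorter than one sample were skipped", n_skipped))
  }
  trials <- if (length(rows)) do.call(rbind, rows) else
    data.frame(onset_s = numeric(0), offset_s = numeric(0),
               duration_s = numeric(0), peak = numeric(0),
               responded = logical(0), latency_s = numeric(0))
  structure(list(
    trials = trials,
    percent_responsive = if (nrow(trials)) 100 * mean(trials$responded) else NA_real_,
    mean_latency_s = if (any(trials$responded))
      mean(trials$latency_s[trials$responded]) else NA_real_,
    mean_bout_duration_s = if (nrow(trials)) mean(trials$duration_s) else NA_real_,
    n_trials = nrow(trials), n_skipped = n_skipped, threshold = threshold),
    class = "trial_response_set")
}

#' @export
print.trial_response_set <- function(x, ...) {
  cat(sprintf("<trial_response_set> %d trial(s): %.1f%% responsive (Z >= %g)",
              x$n_trials, x$percent_responsive, x$threshold))
  if (!is.na(x$mean_latency_s)) {
    cat(sprintf(", mean latency %.2f s", x$mean_latency_s))
  }
  cat(sprintf(", mean bout %.2f s\n", x$mean_bout_duration_s))
  invisible(x)
}

#' Per-stimulus response summary (Z values for the preference index)
#'
#' Computes, for each of the three social stimuli, either the bout-weighted
#' mean Fz during investigation of that stimulus or the introduction peak,
#' producing the Z values the preference index is built from.
#'
#' @param fz An `fz_trace`.
#' @param bouts A merged [bout_table()].
#' @param mode `"investigation_mean"` (default) or `"introduction_peak"`.
#' @param intro_times Named vector of introduction times per stimulus
#'   (required for `"introduction_peak"`).
#' @param stimuli Stimuli to summarize (default male, female, pup).
#' @return Named numeric vector of Z values with attribute `mode`.
#' @export
stimulus_response_summary <- function(fz, bouts,
                                      mode = c("investigation_mean",
                                               "introduction_peak"),
                                      intro_times = NULL,
                                      stimuli = c("male", "female", "pup")) {
  mode <- match.arg(mode)
  z <- vapply(stimuli, function(s) {
    if (mode == "investigation_mean") {
      behavior_mean_fz(fz, bouts, label = "investigation", stimulus = s)
    } else {
      if (is.null(intro_times) || is.na(intro_times[s])) {
        stop("`intro_times` must name every stimulus for introduction_peak mode")
      }
      as.numeric(introduction_peak(fz, intro_times[[s]]))
    }
  }, numeric(1L))
  attr(z, "mode") <- mode
  z
}

#' Stimulus preference index
#'
#' Contrast of the response to one stimulus against the mean response to the
#' other two, normalized to [-1, 1]:
#' `PI_target = (Z_target - 0.5 (Z_a + Z_b)) / (|Z_target| + 0.5 |Z_a + Z_b|)`
#' where a, b are the two non-target stimuli. PI is 1 for an exclusive
#' response to the target, 0 when responses are equal, and undefined when
#' the denominator is 0.
#'
#' @param z Named numeric vector of per-stimulus responses containing
#'   `male`, `female` and `pup` (e.g. from [stimulus_response_summary()]).
#' @param target The stimulus whose preference is scored.
#' @return List of class `preference_index`: `target`, `pi` (`NA` when
#'   undefined), `defined`.
#' @export
preference_index <- function(z, target = c("male", "female", "pup")) {
  target <- match.arg(target)
  need <- c("male", "female", "pup")
  if (!all(need %in% names(z)) || anyNA(z[need])) {
    stop("`z` must provide finite values named male, female and pup")
  }
  others <- setdiff(need, target)
  num <- z[[target]] - 0.5 * (z[[others[1L]]] + z[[others[2L]]])
  den <- abs(z[[target]]) + 0.5 * abs(z[[others[1L]]] + z[[others[2L]]])
  structure(list(target = target,
                 pi = if (den == 0) NA_real_ else num / den,
                 defined = den != 0),
            class = "preference_index")
}

#' @export
print.preference_index <- function(x, ...) {
  cat(sprintf("<preference_index> PI_%s = %s\n", x$target,
              if (x$defined) sprintf("%.3f", x$pi) else "undefined"))
  invisible(x)
}

#' Time for an offset-aligned PETH to return toward baseline
#'
#' Quantifies how long the population response takes to fall back to `frac`
#' (default 10%) of its value at the alignment point — the measure that
#' separates slow post-bout decay (>10 s) from fast decay (<3 s).
#'
#' Because the whole-trace z-score places the quiet baseline below zero, the
#' post-offset PETH decays toward a non-zero asymptote. The default
#' `"fit"` method therefore fits a single exponential
#' `b + (v0 - b) exp(-t / tau)` to the post-alignment mean and reports
#' `tau * log(1 / frac)`, the time at which the fitted decay has covered all
#' but `frac` of its range. The `"crossing"` method instead returns the
#' first bin whose mean drops below `frac` times the time-0 value (biased
#' early whenever the asymptote is below zero).
#'
#' @param peth A `peth_result` aligned to bout offsets.
#' @param frac Remaining fraction defining the return time (default 0.1).
#' @param method `"fit"` (exponential fit, default) or `"crossing"`.
#' @return Decay time in seconds, or `NA` when the PETH has no positive
#'   deflection at time 0 (or, for `"crossing"`, never falls below the
#'   threshold inside the window).
#' @export
peth_decay_time <- function(peth, frac = 0.1, method = c("fit", "crossing")) {
  method <- match.arg(method)
  stopifnot(inherits(peth, "peth_result"), !peth$empty)
  i0 <- which.min(abs(peth$time))
  v0 <- peth$mean[i0]
  if (!is.finite(v0) || v0 <= 0) return(NA_real_)
  post <- which(peth$time >= 0)
  if (method == "crossing") {
    below <- post[peth$mean[post] < frac * v0]
    return(if (length(below)) peth$time[below[1L]] else NA_real_)
  }
  df <- data.frame(t = peth$time[post], y = peth$mean[post])
  df <- df[is.finite(df$y), , drop = FALSE]
  fit <- tryCatch(
    stats::nls(y ~ SSasymp(t, Asym, R0, lrc), data = df),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the direct crossing relative to the tail level
    b <- mean(utils::tail(df$y, max(3L, round(nrow(df) * 0.05))))
    below <- which(df$y - b < frac * (v0 - b) & df$t > 0)
    return(if (length(below)) df$t[below[1L]] else NA_real_)
  }
  tau <- 1 / exp(stats::coef(fit)[["lrc"]])
  tau * log(1 / frac)
}
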