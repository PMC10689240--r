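#' Voltage-clamp sweep set for optogenetic PSC analysis
#'
#' A set of repeated sweeps recorded while a brief light pulse activates
#' opsin-expressing axons. The holding potential sets the expected current
#' sign: inward (negative) evoked EPSCs at -70 mV, outward (positive)
#' evoked IPSCs at 0 mV.
#'
#' @param time_ms Sample times, ms, uniform grid.
#' @param current Samples x sweeps numeric matrix of membrane current, pA.
#' @param fs Sampling rate, Hz.
#' @param light_onset_ms Light pulse onset within the sweep, ms.
#' @param holding_mV Holding potential, -70 or 0 mV.
#' @param condition Pharmacological condition: `"ACSF"`, `"TTX"` or
#'   `"TTX+4AP"`.
#' @param pulse_ms Light pulse width, ms (default 1).
#' @return A list of class `psc_sweep_set`.
#' @export
psc_sweep_set <- function(time_ms, current, fs, light_onset_ms, holding_mV,
                          condition = c("ACSF", "TTX", "TTX+4AP"),
                          pulse_ms = 1) {
  condition <- match.arg(condition)
  current <- as.matrix(current)
  if (length(time_ms) != nrow(current)) {
    stop("`current` must have one row per sample")
  }
  if (!holding_mV %in% c(-70, 0)) stop("`holding_mV` must be -70 or 0")
  if (light_onset_ms < time_ms[1L] || light_onset_ms > time_ms[length(time_ms)]) {
    stop("`light_onset_ms` must lie within the sweep")
  }
  structure(list(time_ms = as.numeric(time_ms), current = current, fs = fs,
                 light_onset_ms = light_onset_ms, holding_mV = holding_mV,
                 condition = condition, pulse_ms = pulse_ms),
            class = "psc_sweep_set")
}

#' @export
print.psc_sweep_set <- function(x, ...) {
  cat(sprintf("<psc_sweep_set> %d sweep(s) x %d samples @ %g kHz, %s, %g mV, light at %g ms\n",
              ncol(x$current), nrow(x$current), x$fs / 1000, x$condition,
              x$holding_mV, x$light_onset_ms))
  invisible(x)
}

#' Detect an optogenetically evoked PSC in a sweep set
#'
#' Averages across sweeps, measures the baseline mean and SD over a window
#' ending at light onset, and searches after light onset for a deflection in
#' the direction expected from the holding potential (inward at -70 mV,
#' outward at 0 mV). The cell is responsive when the deflection strictly
#' exceeds 1.5 times the baseline SD; latency is the time from light onset
#' to the first such crossing, and amplitude is the magnitude of the
#' baseline-subtracted extremum of the mean sweep in the search window.
#'
#' A synaptic current lasts milliseconds, while threshold crossings from
#' acquisition noise at 20 kHz last single samples; the crossing must
#' therefore be sustained for `min_duration_ms` (default 1 ms, the light
#' pulse width) to count as a response. Latency is taken at the first sample
#' of the first sustained crossing.
#'
#' @param sweeps A [psc_sweep_set()].
#' @param baseline_ms Baseline window length ending at light onset, ms
#'   (default 50).
#' @param search_ms Search window after light onset, ms (default 50; covers
#'   both short monosynaptic ~4 ms and long polysynaptic >10 ms latencies).
#' @param k Threshold in baseline SD units (default 1.5).
#' @param min_duration_ms Minimum time the deflection must stay above
#'   threshold, ms.
#' @return An object of class `psc_event`: `responsive`, `amplitude_pA`,
#'   `latency_ms` (`NA` unless responsive), `type` (`"oEPSC"` at -70 mV,
#'   `"oIPSC"` at 0 mV), `condition`, `baseline_sd`.
#' @export
detect_psc <- function(sweeps, baseline_ms = 50, search_ms = 50, k = 1.5,
                       min_duration_ms = 1) {
  stopifnot(inherits(sweeps, "psc_sweep_set"))
  t <- sweeps$time_ms
  on <- sweeps$light_onset_ms
  if (on - baseline_ms < t[1L] - 1e-9) {
    stop("baseline window extends before the start of the sweep")
  }
  m <- rowMeans(sweeps$current)
  base_idx <- which(t >= on - baseline_ms & t < on)
  if (length(base_idx) < 2L) stop("baseline window contains fewer than two samples")
  mu <- mean(m[base_idx])
  sd0 <- stats::sd(m[base_idx])
  sgn <- if (sweeps$holding_mV == -70) -1 else 1

  search_idx <- which(t >= on & t <= on + search_ms)
  defl <- sgn * (m[search_idx] - mu)      # positive = expected direction
  above <- defl > k * sd0                 # strict exceedance
  min_run <- max(1L, ceiling(min_duration_ms * sweeps$fs / 1000))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  runs <- which(r$values & r$lengths >= min_run)
  responsive <- length(runs) > 0L
  first <- if (responsive) ends[runs[1L]] - r$lengths[runs[1L]] + 1L else NA_integer_
  structure(list(
    responsive = responsive,
    amplitude_pA = max(defl),
    latency_ms = if (responsive) t[search_idx[first]] - on else NA_real_,
    type = if (sweeps$holding_mV == -70) "oEPSC" else "oIPSC",
    condition = sweeps$condition,
    baseline_sd = sd0),
    class = "psc_event")
}

#' @export
print.psc_event <- function(x, ...) {
  if (x$responsive) {
    cat(sprintf("<psc_event> %s (%s): responsive, amplitude %.1f pA, latency %.2f ms\n",
                x$type, x$condition, x$amplitude_pA, x$latency_ms))
  } else {
    cat(sprintf("<psc_event> %s (%s): non-responsive\n", x$type, x$condition))
  }
  invisible(x)
}

#' Classify a light-evoked connection from pharmacology
#'
#' Monosynaptic connections survive action-potential blockade when
#' potassium channels are also blocked: the response is abolished by TTX and
#' recovered by TTX + 4-AP. Polysynaptic responses are abolished by TTX and
#' fail to recover with 4-AP.
#'
#' @param events Named list of `psc_event`s (or logical responsiveness
#'   flags) with element `ACSF` required and `TTX`, `TTX+4AP` optional.
#' @return One of `"monosynaptic"`, `"polysynaptic"`, `"none"`,
#'   `"unclassifiable"` (pharmacology missing) or `"inconsistent"` (response
#'   persisting in TTX alone).
#' @export
classify_connection <- function(events) {
  resp <- function(e) {
    if (is.null(e)) return(NA)
    if (is.logical(e)) return(e)
    if (inherits(e, "psc_event")) return(e$responsive)
    stop("events must be psc_event objects or logicals")
  }
  if (is.null(events$ACSF)) stop("the ACSF condition is required")
  acsf <- resp(events$ACSF)
  ttx <- resp(events$TTX)
  ttx4ap <- resp(events$`TTX+4AP`)
  if (!acsf) return("none")
  if (is.na(ttx) || is.na(ttx4ap)) return("unclassifiable")
  if (ttx) return("inconsistent")
  if (ttx4ap) "monosynaptic" else "polysynaptic"
}
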