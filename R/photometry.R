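#' Photometry trace container
#'
#' A uniformly sampled raw fluorescence trace. All downstream signal
#' processing (baseline estimation, dF/F, whole-trace z-scoring) starts from
#' this object.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   on a uniform grid.
#' @param f_raw Numeric vector of raw fluorescence values (arbitrary units),
#'   same length as `time`, all finite.
#' @param fs Sampling rate in Hz. Must agree with the spacing of `time` to
#'   within 1e-6 s.
#' @return An object of class `photometry_trace` with elements `time`,
#'   `f_raw` and `fs`.
#' @examples
#' tr <- photometry_trace(seq(0, 10, by = 0.04), rnorm(251, 100, 1), fs = 25)
#' tr
#' @export
photometry_trace <- function(time, f_raw, fs) {
  stopifnot(is.numeric(time), is.numeric(f_raw))
  if (length(time) != length(f_raw)) {
    stop("`time` and `f_raw` must have the same length")
  }
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (anyNA(f_raw) || any(!is.finite(f_raw))) {
    stop("`f_raw` contains missing or non-finite samples; traces must be gap-free")
  }
  if (length(time) >= 2L) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("`time` must be strictly increasing")
    if (max(abs(dt - 1 / fs)) > 1e-6) {
      stop("`time` is not a uniform grid at the stated sampling rate `fs`")
    }
  }
  structure(list(time = as.numeric(time), f_raw = as.numeric(f_raw),
                 fs = as.numeric(fs)),
            class = "photometry_trace")
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> %d samples @ %g Hz (%.1f s), F_raw range [%.3g, %.3g]\n",
              length(x$time), x$fs, diff(range(x$time)),
              min(x$f_raw), max(x$f_raw)))
  invisible(x)
}

#' Baseline estimation settings
#'
#' Parameters for the sliding-window quantile baseline estimator. The window
#' spans a fixed fraction of the total recording (default 25%); within each
#' window a low quantile of the raw signal is taken as a baseline anchor, and
#' anchors are interpolated back onto the full sample grid.
#'
#' The default quantile (0.10) tracks the lower envelope of a trace that
#' carries positive-going transients. For transient-free signals (e.g. a pure
#' bleaching drift) `quantile = 0.5` is the unbiased choice: the median of a
#' monotone signal within a window equals its value at the window center.
#'
#' @param window_fraction Window length as a fraction of total trace duration
#'   (0 < window_fraction <= 1). Default 0.25.
#' @param stride_fraction Anchor spacing as a fraction of the window length.
#'   Default 0.2 (five anchors per window length).
#' @param quantile Quantile of the raw signal taken inside each window,
#'   in (0, 1). Default 0.10.
#' @param interpolation Either `"spline"` (natural cubic spline through the
#'   anchors) or `"linear"`.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(window_fraction = 0.25, stride_fraction = 0.2,
                            quantile = 0.10,
                            interpolation = c("spline", "linear")) {
  interpolation <- match.arg(interpolation)
  if (!(window_fraction > 0 && window_fraction <= 1)) {
    stop("`window_fraction` must be in (0, 1]")
  }
  if (!(stride_fraction > 0 && stride_fraction <= 1)) {
    stop("`stride_fraction` must be in (0, 1]")
  }
  if (!(quantile > 0 && quantile < 1)) stop("`quantile` must be in (0, 1)")
  structure(list(window_fraction = window_fraction,
                 stride_fraction = stride_fraction,
                 quantile = quantile,
                 interpolation = interpolation),
            class = "baseline_config")
}

#' Estimate the instantaneous fluorescence baseline
#'
#' Slides a window of `window_fraction` of the total recording time across
#' the trace; at each window position the configured low quantile of `F_raw`
#' is taken as a baseline anchor, placed at the center of the (possibly
#' edge-truncated) window. Anchors are interpolated onto the full sample grid.
#' Edge windows are truncated rather than padded, so no data are fabricated
#' beyond the recording.
#'
#' @param trace A [photometry_trace()].
#' @param cfg A [baseline_config()].
#' @return Numeric baseline vector on the same grid as `trace$time`.
#' @export
estimate_baseline <- function(trace, cfg = baseline_config()) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (!inherits(cfg, "baseline_config")) stop("`cfg` must be a baseline_config")
  n <- length(trace$time)
  t0 <- trace$time[1L]
  total <- trace$time[n] - t0
  w <- cfg$window_fraction * total
  if (w <= 0 || n < 4L) stop("trace too short for baseline estimation")
  stride <- cfg$stride_fraction * w
  centers <- seq(0, total, by = stride)
  if (centers[length(centers)] < total) centers <- c(centers, total)

  rel <- trace$time - t0
  anchor_t <- numeric(length(centers))
  anchor_v <- numeric(length(centers))
  for (i in seq_along(centers)) {
    lo <- max(0, centers[i] - w / 2)
    hi <- min(total, centers[i] + w / 2)
    idx <- which(rel >= lo - 1e-9 & rel <= hi + 1e-9)
    anchor_t[i] <- mean(range(rel[idx]))
    anchor_v[i] <- stats::quantile(trace$f_raw[idx], probs = cfg$quantile,
                                   names = FALSE, type = 7)
  }
  keep <- !duplicated(round(anchor_t, 9))
  anchor_t <- anchor_t[keep]
  anchor_v <- anchor_v[keep]
  if (length(anchor_t) < 2L) return(rep(anchor_v[1L], n))

  if (cfg$interpolation == "spline") {
    out <- stats::spline(anchor_t, anchor_v, xout = rel, method = "natural")$y
  } else {
    out <- stats::approx(anchor_t, anchor_v, xout = rel, rule = 2)$y
  }
  out
}

#' Compute dF/F from a raw trace and its baseline
#'
#' The instantaneous fractional fluorescence change
#' `(F_raw - F_baseline) / F_baseline`, sample by sample.
#'
#' @param trace A [photometry_trace()].
#' @param baseline Numeric baseline vector on the same grid, strictly
#'   positive everywhere.
#' @return An object of class `dff_trace` with elements `time`, `dff`, `fs`.
#' @export
compute_dff <- function(trace, baseline) {
  stopifnot(inherits(trace, "photometry_trace"))
  if (length(baseline) != length(trace$f_raw)) {
    stop("`baseline` must match the trace length")
  }
  bad <- which(baseline <= 0)
  if (length(bad)) {
    stop(sprintf("baseline is non-positive at sample %d (t = %.4f s)",
                 bad[1L], trace$time[bad[1L]]))
  }
  structure(list(time = trace$time,
                 dff = (trace$f_raw - baseline) / baseline,
                 fs = trace$fs),
            class = "dff_trace")
}

#' Whole-trace z-score (Fz)
#'
#' Standardizes a dF/F trace over its entire duration:
#' `Fz = (dff - mean(dff)) / sd(dff)` with the sample (n - 1) standard
#' deviation. The result has mean 0 and SD 1 by construction and is the unit
#' in which all downstream response metrics are expressed.
#'
#' @param dff A `dff_trace` from [compute_dff()], or any list/data frame with
#'   numeric `time` and `dff` elements and an `fs`.
#' @return An object of class `fz_trace` with elements `time`, `fz`, `fs`.
#' @export
zscore_trace <- function(dff) {
  x <- dff$dff
  if (is.null(x)) stop("`dff` must contain a `dff` element")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("dF/F trace has zero variance; cannot z-score")
  structure(list(time = dff$time, fz = (x - mean(x)) / s, fs = dff$fs),
            class = "fz_trace")
}

#' @export
print.fz_trace <- function(x, ...) {
  cat(sprintf("<fz_trace> %d samples @ %g Hz, range [%.2f, %.2f] SD\n",
              length(x$time), x$fs, min(x$fz), max(x$fz)))
  invisible(x)
}

#' Raw trace to Fz in one call
#'
#' Convenience wrapper: [estimate_baseline()], [compute_dff()],
#' [zscore_trace()].
#'
#' @inheritParams estimate_baseline
#' @return An `fz_trace`; the baseline and dff are attached as attributes
#'   `baseline` and `dff`.
#' @export
preprocess_trace <- function(trace, cfg = baseline_config()) {
  bl <- estimate_baseline(trace, cfg)
  dff <- compute_dff(trace, bl)
  fz <- zscore_trace(dff)
  attr(fz, "baseline") <- bl
  attr(fz, "dff") <- dff$dff
  fz
}

# Internal: coerce anything with time + fz (or a bare fz_trace) to a
# two-column representation used by the event metrics.
as_fz <- function(fz) {
  if (inherits(fz, "fz_trace")) return(fz)
  if (is.list(fz) && !is.null(fz$time) && !is.null(fz$fz)) {
    fs <- fz$fs
    if (is.null(fs)) fs <- 1 / stats::median(diff(fz$time))
    return(structure(list(time = fz$time, fz = fz$fz, fs = fs),
                     class = "fz_trace"))
  }
  stop("expected an fz_trace or a list with `time` and `fz`")
}
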