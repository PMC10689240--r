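#' Peri-event time histogram of Fz aligned to behavior onsets or offsets
#'
#' Extracts an Fz snippet around every bout of the requested behavior,
#' resampled onto a common bin grid (linear interpolation of the trace), and
#' averages hierarchically: trials within an animal are averaged to a
#' per-animal mean, then the grand mean and s.e.m. are taken across animals.
#' Trials keep their raw Fz values; no per-trial renormalization is applied.
#' Windows extending beyond the recording are truncated (missing bins are
#' `NA` and are dropped from the means).
#'
#' With two or more animals, a pointwise one-sample t-test against Fz = 0 is
#' run per bin and corrected across bins with Benjamini-Hochberg FDR;
#' the significance mask flags bins with q below the configured level and a
#' positive grand mean (significantly increased responses).
#'
#' @param fz An `fz_trace` (one animal) or a list of `fz_trace`s (one per
#'   animal).
#' @param bouts A [bout_table()] or a parallel list of them.
#' @param label Behavior label to align to (default `"investigation"`).
#' @param stimulus Optional stimulus filter.
#' @param align Align to bout `"onset"` or `"offset"`.
#' @param window_pre,window_post Window before/after the alignment point, s.
#' @param bin Bin width, s.
#' @param stats_cfg A [stats_config()] controlling the pointwise test.
#' @return An object of class `peth_result`: `time` (bin grid, includes 0),
#'   `trials` (trials x bins matrix, pooled across animals), `animal_means`
#'   (animals x bins), `mean`, `sem`, `mask` (logical per bin, `NULL` when
#'   fewer than two animals), `align`, `n_animals`, `empty`.
#' @export
compute_peth <- function(fz, bouts, label = "investigation", stimulus = NULL,
                         align = c("onset", "offset"),
                         window_pre = 10, window_post = 20, bin = 0.2,
                         stats_cfg = stats_config()) {
  align <- match.arg(align)
  if (inherits(fz, "fz_trace")) fz <- list(fz)
  if (inherits(bouts, "bout_table")) bouts <- list(bouts)
  if (length(fz) != length(bouts)) {
    stop("`fz` and `bouts` must have one element per animal")
  }
  grid <- c(rev(seq(0, -window_pre, by = -bin)), seq(bin, window_post, by = bin))
  n_bins <- length(grid)

  per_animal <- vector("list", length(fz))
  trials <- list()
  for (a in seq_along(fz)) {
    tr <- as_fz(fz[[a]])
    bt <- as.data.frame(bouts[[a]])
    sel <- bt$behavior == label
    if (!is.null(stimulus)) sel <- sel & bt$stimulus == stimulus
    ev <- if (align == "onset") bt$onset_s[sel] else bt$offset_s[sel]
    if (!length(ev)) next
    mat <- t(vapply(ev, function(e) {
      stats::approx(tr$time, tr$fz, xout = e + grid, rule = 1)$y
    }, numeric(n_bins)))
    per_animal[[a]] <- colMeans(mat, na.rm = TRUE)
    trials[[length(trials) + 1L]] <- mat
  }
  keep <- !vapply(per_animal, is.null, logical(1L))
  if (!any(keep)) {
    return(structure(list(time = grid, trials = NULL, animal_means = NULL,
                          mean = NULL, sem = NULL, mask = NULL,
                          align = align, n_animals = 0L, empty = TRUE),
                     class = "peth_result"))
  }
  am <- do.call(rbind, per_animal[keep])
  n_animals <- nrow(am)
  grand <- colMeans(am, na.rm = TRUE)
  sem <- if (n_animals > 1L) {
    apply(am, 2L, function(v) stats::sd(v, na.rm = TRUE)) / sqrt(n_animals)
  } else rep(0, n_bins)
  mask <- if (n_animals >= 2L) pointwise_onesample_fdr(am, stats_cfg)$mask else NULL
  structure(list(time = grid, trials = do.call(rbind, trials),
                 animal_means = am, mean = grand, sem = sem, mask = mask,
                 align = align, n_animals = n_animals, empty = FALSE),
            class = "peth_result")
}

#' @export
print.peth_result <- function(x, ...) {
  if (x$empty) {
    cat("<peth_result> empty (no bouts matched)\n")
    return(invisible(x))
  }
  cat(sprintf("<peth_result> %s-aligned, %d bins [%g, %g] s, %d trial(s), %d animal(s)",
              x$align, length(x$time), min(x$time), max(x$time),
              nrow(x$trials), x$n_animals))
  if (!is.null(x$mask)) cat(sprintf(", %d bin(s) flagged", sum(x$mask)))
  cat("\n")
  invisible(x)
}

#' Pointwise-test settings
#'
#' @param q FDR level for the Benjamini-Hochberg correction across bins
#'   (default 0.05).
#' @return A list of class `stats_config`.
#' @export
stats_config <- function(q = 0.05) {
  if (!(q > 0 && q < 1)) stop("`q` must be in (0, 1)")
  structure(list(q = q), class = "stats_config")
}

#' Pointwise one-sample t-tests across PETH bins with BH-FDR correction
#'
#' For each bin, tests the per-animal means against the null hypothesis
#' Fz = 0 (two-tailed one-sample t-test), then applies the Benjamini-Hochberg
#' step-up procedure across bins. The returned mask flags bins that are
#' rejected at level q *and* have a positive mean, i.e. significantly
#' increased responses.
#'
#' @param mat Animals x bins matrix of per-animal PETH means (>= 2 rows).
#' @param cfg A [stats_config()].
#' @return List with `p` (per-bin p-values), `rejected` (indices rejected by
#'   BH at level q) and `mask` (logical: rejected and mean > 0).
#' @export
pointwise_onesample_fdr <- function(mat, cfg = stats_config()) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("at least two animals are required")
  p <- apply(mat, 2L, function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2L) return(NA_real_)
    s <- stats::sd(v)
    m <- mean(v)
    if (s == 0) return(if (m == 0) 1 else 0)
    tt <- m / (s / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1L)
  })
  p_use <- ifelse(is.na(p), 1, p)
  rej <- bh_fdr(p_use, cfg$q)
  mask <- rep(FALSE, ncol(mat))
  mask[rej] <- TRUE
  mask <- mask & colMeans(mat, na.rm = TRUE) > 0
  list(p = p, rejected = rej, mask = mask)
}

#' Benjamini-Hochberg step-up rejection set
#'
#' Implements the original Benjamini-Hochberg false-discovery-rate
#' procedure: with sorted p-values p(1) <= ... <= p(m), find
#' k* = max\{k : p(k) <= k q / m\} and reject the hypotheses with the k*
#' smallest p-values. Tied p-values share the same fate.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return Integer indices (into `p`) of the rejected hypotheses; empty when
#'   nothing is rejected.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(integer(0))
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(integer(0))
  k <- max(ok)
  # ties with p(k*) share its fate
  which(p <= ps[k])
}
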