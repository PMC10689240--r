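#' @name behavior
#' @title Behavior bout tables and body tracking
#' @description Validated bout tables (closed label vocabulary, half-open
#'   `[onset, offset)` intervals in seconds), the investigation/groom merge
#'   rule used for photometry analysis, classification of investigation bouts
#'   by whether an attack follows, and mean locomotion velocity from position
#'   tracks.
NULL

STIMULI <- c("male", "female", "pup", "object")
BEHAVIOR_LABELS <- c("investigation", "groom", "attack", "mount",
                     "intromission", "ejaculation", "infanticide",
                     "introduction")

#' Construct and validate a bout table
#'
#' @param df Data frame with columns `session`, `stimulus`, `behavior`,
#'   `onset_s`, `offset_s`. Stimuli must be one of male/female/pup/object;
#'   behavior labels come from the closed vocabulary (investigation, groom,
#'   attack, mount, intromission, ejaculation, infanticide, introduction).
#'   Bouts are half-open intervals `[onset_s, offset_s)`; same-label bouts
#'   within a session must not overlap.
#' @return The validated data frame with class `bout_table`, sorted by
#'   session and onset.
#' @export
bout_table <- function(df) {
  req <- c("session", "stimulus", "behavior", "onset_s", "offset_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$session <- as.character(df$session)
  df$stimulus <- as.character(df$stimulus)
  df$behavior <- as.character(df$behavior)

  bad <- which(!df$stimulus %in% STIMULI)
  if (length(bad)) {
    stop(sprintf("row %d: unknown stimulus '%s'", bad[1L], df$stimulus[bad[1L]]))
  }
  bad <- which(!df$behavior %in% BEHAVIOR_LABELS)
  if (length(bad)) {
    stop(sprintf("row %d: unknown behavior label '%s'", bad[1L], df$behavior[bad[1L]]))
  }
  bad <- which(!(df$offset_s > df$onset_s))
  if (length(bad)) {
    stop(sprintf("row %d: offset (%.3f) must exceed onset (%.3f)",
                 bad[1L], df$offset_s[bad[1L]], df$onset_s[bad[1L]]))
  }
  ord <- order(df$session, df$onset_s, df$offset_s)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  for (key in unique(paste(df$session, df$behavior))) {
    sub <- df[paste(df$session, df$behavior) == key, , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$onset_s[-1L] < sub$offset_s[-nrow(sub)] - 1e-9)) {
      stop("overlapping same-label bouts within a session: ", key)
    }
  }
  class(df) <- c("bout_table", "data.frame")
  df
}

#' Read a bout table from a delimited file
#'
#' @param path CSV file with columns `session`, `stimulus`, `behavior`,
#'   `onset_s`, `offset_s`.
#' @return A validated [bout_table()].
#' @export
load_bouts <- function(path) {
  if (!file.exists(path)) stop("bout file not found: ", path)
  bout_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a bout table to CSV
#' @param bouts A [bout_table()].
#' @param path Output file path.
#' @export
write_bouts <- function(bouts, path) {
  utils::write.csv(as.data.frame(bouts), path, row.names = FALSE)
  invisible(path)
}

#' Merge grooming into investigation and coalesce abutting bouts
#'
#' For photometry analysis, grooming of a conspecific is scored together with
#' investigation: groom bouts are relabeled `investigation` (per stimulus, so
#' pup grooming becomes pup investigation), and same-label bouts that overlap
#' or abut within `gap_tol` seconds are coalesced into a single bout spanning
#' the earliest onset to the latest offset. Other labels (attack, mount, ...)
#' are untouched.
#'
#' @param bouts A [bout_table()].
#' @param gap_tol Bouts of the same label separated by less than this gap (s)
#'   are coalesced; default 0.04 s, one frame at the 25 frames/s annotation
#'   rate.
#' @return A [bout_table()].
#' @export
merge_labels <- function(bouts, gap_tol = 0.04) {
  stopifnot(inherits(bouts, "bout_table"))
  df <- as.data.frame(bouts)
  df$behavior[df$behavior == "groom"] <- "investigation"
  pieces <- split(df, paste(df$session, df$stimulus, df$behavior, sep = "\r"))
  out <- lapply(pieces, function(sub) {
    sub <- sub[order(sub$onset_s), , drop = FALSE]
    if (nrow(sub) <= 1L) return(sub)
    keep_on <- sub$onset_s[1L]
    keep_off <- sub$offset_s[1L]
    res <- sub[0L, , drop = FALSE]
    for (i in seq_len(nrow(sub))[-1L]) {
      if (sub$onset_s[i] <= keep_off + gap_tol) {
        keep_off <- max(keep_off, sub$offset_s[i])
      } else {
        res <- rbind(res, data.frame(session = sub$session[1L],
                                     stimulus = sub$stimulus[1L],
                                     behavior = sub$behavior[1L],
                                     onset_s = keep_on, offset_s = keep_off))
        keep_on <- sub$onset_s[i]
        keep_off <- sub$offset_s[i]
      }
    }
    rbind(res, data.frame(session = sub$session[1L], stimulus = sub$stimulus[1L],
                          behavior = sub$behavior[1L],
                          onset_s = keep_on, offset_s = keep_off))
  })
  bout_table(do.call(rbind, c(out, list(make.row.names = FALSE))))
}

#' Classify investigation bouts by whether an attack follows
#'
#' An investigation bout is `followed_by_attack` if and only if some attack
#' bout starts within `[offset, offset + gap_max]` of its offset. The
#' partition of investigation bouts is exhaustive and disjoint.
#'
#' @param bouts A merged [bout_table()] for a male-intruder session.
#' @param gap_max Maximum allowed gap (s) between investigation offset and
#'   attack onset; default 1 s. With `gap_max = 0`, only attacks starting
#'   exactly at the investigation offset qualify.
#' @return The investigation rows of `bouts` with an added logical column
#'   `followed_by_attack`.
#' @export
split_investigations_by_attack <- function(bouts, gap_max = 1) {
  stopifnot(inherits(bouts, "bout_table"))
  if (gap_max < 0) stop("`gap_max` must be non-negative")
  df <- as.data.frame(bouts)
  inv <- df[df$behavior == "investigation", , drop = FALSE]
  atk <- df[df$behavior == "attack", , drop = FALSE]
  inv$followed_by_attack <- vapply(seq_len(nrow(inv)), function(i) {
    same <- atk$session == inv$session[i]
    any(same &
          atk$onset_s >= inv$offset_s[i] - 1e-9 &
          atk$onset_s <= inv$offset_s[i] + gap_max + 1e-9)
  }, logical(1L))
  rownames(inv) <- NULL
  inv
}

#' Construct a position track
#'
#' @param frame Integer frame indices, consecutive.
#' @param x,y Pixel coordinates, finite.
#' @param fps Frame rate in frames per second (default 25).
#' @return A data frame of class `track_series`.
#' @export
track_series <- function(frame, x, y, fps = 25) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  if (length(frame) >= 2L && any(diff(frame) != 1L)) {
    stop("frames must be consecutive")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite")
  }
  structure(data.frame(frame = frame, x = x, y = y),
            fps = fps, class = c("track_series", "data.frame"))
}

#' Mean locomotion velocity in pixels per frame
#'
#' Per-frame Euclidean displacement, averaged over the first `window`
#' seconds of the track (default 300 s, i.e. the first 5 minutes before any
#' stimulus is introduced).
#'
#' @param track A [track_series()].
#' @param window Averaging window in seconds from the start of the track.
#' @return Mean velocity in pixels/frame.
#' @export
compute_velocity <- function(track, window = 300) {
  stopifnot(inherits(track, "track_series"))
  fps <- attr(track, "fps")
  n_frames <- min(nrow(track), ceiling(window * fps))
  if (window * fps > nrow(track)) {
    stop("`window` exceeds the track duration")
  }
  dx <- diff(track$x[seq_len(n_frames)])
  dy <- diff(track$y[seq_len(n_frames)])
  mean(sqrt(dx^2 + dy^2))
}
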