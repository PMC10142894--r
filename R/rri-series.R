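#' Construct an RR-interval series
#'
#' An `rri_series` holds one continuous recording of inter-beat (RR)
#' intervals: for each detected heartbeat the time of the beat in seconds
#' from recording onset and the RR interval, in milliseconds, ending at that
#' beat. When beat times are not supplied they are reconstructed as the
#' cumulative sum of the intervals, which is exact for sensors that derive
#' beat times from the intervals themselves.
#'
#' @param rri numeric vector of RR intervals in milliseconds; all positive.
#' @param t optional numeric vector of beat times in seconds, strictly
#'   increasing, same length as `rri`. Defaults to `cumsum(rri) / 1000`.
#' @param session_id character scalar identifying the recording.
#' @param gap_before optional logical vector; `TRUE` marks a beat whose
#'   predecessor was removed (e.g. by [reject_artifacts()]), so the
#'   difference across that boundary must not be treated as a true
#'   beat-to-beat difference.
#'
#' @return A data frame of class `rri_series` with columns `t`, `rri` and
#'   `gap_before`, and attribute `session_id`.
#' @export
#' @examples
#' rri_series(c(800, 810, 795), session_id = "s1")
rri_series <- function(rri, t = NULL, session_id = "session",
                       gap_before = NULL) {
  rri <- as.numeric(rri)
  if (length(rri) && any(!is.finite(rri) | rri <= 0)) {
    bad <- which(!is.finite(rri) | rri <= 0)
    stop("non-positive or non-finite RRI at row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)
  }
  if (is.null(t)) {
    t <- cumsum(rri) / 1000
  } else {
    t <- as.numeric(t)
    if (length(t) != length(rri)) {
      stop("`t` and `rri` must have the same length", call. = FALSE)
    }
    if (length(t) > 1L && any(diff(t) <= 0)) {
      stop("beat times must be strictly increasing", call. = FALSE)
    }
  }
  if (is.null(gap_before)) {
    gap_before <- rep(FALSE, length(rri))
  } else {
    stopifnot(length(gap_before) == length(rri))
  }
  out <- data.frame(t = t, rri = rri, gap_before = as.logical(gap_before))
  attr(out, "session_id") <- as.character(session_id)
  class(out) <- c("rri_series", "data.frame")
  out
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> session '%s': %d beats", session_id(x), nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", %.1f s, mean RRI %.1f ms", x$t[nrow(x)] - x$t[1L] + x$rri[1L] / 1000,
                mean(x$rri)))
  }
  cat("\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Session identifier of an object
#' @param x an `rri_series` or `event_track`.
#' @return Character scalar.
#' @export
session_id <- function(x) attr(x, "session_id")

#' Construct an event track
#'
#' An `event_track` carries the behavioural annotations for one recording:
#' nod onset times, sleep intervals, the experimental condition and which
#' half of the session the recording belongs to.
#'
#' @param nods numeric vector of nod onset times in seconds from recording
#'   start. Sorted ascending and de-duplicated (with a warning) on input.
#' @param sleep data frame with columns `start`, `end` (seconds) of sleep
#'   spans, or `NULL` for none.
#' @param condition one of `"no_nodding_video"`, `"with_video_not_forced"`,
#'   `"with_video_forced"`.
#' @param half `"first"` or `"second"`: which lecture half the recording is.
#' @param session_id character scalar identifying the recording.
#'
#' @return A list of class `event_track`.
#' @export
event_track <- function(nods = numeric(), sleep = NULL,
                        condition = c("no_nodding_video",
                                      "with_video_not_forced",
                                      "with_video_forced"),
                        half = c("second", "first"),
                        session_id = "session") {
  condition <- match.arg(condition)
  half <- match.arg(half)
  nods <- as.numeric(nods)
  if (any(!is.finite(nods))) stop("nod times must be finite", call. = FALSE)
  if (is.unsorted(nods, strictly = FALSE)) {
    warning("nod times not ascending; sorting", call. = FALSE)
    nods <- sort(nods)
  }
  if (anyDuplicated(nods)) {
    warning("duplicate nod times removed", call. = FALSE)
    nods <- unique(nods)
  }
  if (is.null(sleep)) sleep <- data.frame(start = numeric(), end = numeric())
  sleep <- as.data.frame(sleep)[, c("start", "end")]
  if (nrow(sleep)) {
    if (any(sleep$end <= sleep$start)) {
      stop("sleep intervals must have start < end", call. = FALSE)
    }
    sleep <- normalize_intervals(sleep$start, sleep$end)
  }
  structure(
    list(session_id = as.character(session_id), condition = condition,
         half = half, nods = nods, sleep = sleep),
    class = "event_track")
}

#' @export
print.event_track <- function(x, ...) {
  cat(sprintf("<event_track> session '%s' (%s, %s half): %d nods, %d sleep spans\n",
              x$session_id, x$condition, x$half, length(x$nods), nrow(x$sleep)))
  invisible(x)
}

# Merge overlapping/touching intervals into a disjoint ascending set.
normalize_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(), end = numeric()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ns <- start[1L]; ne <- end[1L]
  os <- numeric(); oe <- numeric()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= ne) {
      ne <- max(ne, end[i])
    } else {
      os <- c(os, ns); oe <- c(oe, ne)
      ns <- start[i]; ne <- end[i]
    }
  }
  data.frame(start = c(os, ns), end = c(oe, ne))
}

# TRUE for each x that lies inside any [start, end] interval.
in_intervals <- function(x, intervals) {
  if (!nrow(intervals)) return(rep(FALSE, length(x)))
  idx <- findInterval(x, intervals$start)
  idx > 0L & x <= intervals$end[pmax(idx, 1L)]
}
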