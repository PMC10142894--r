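#' Sliding-window pNN50 series
#'
#' pNN50 is the proportion of adjacent beat pairs whose RR intervals differ
#' by more than 50 ms (strictly: a difference of exactly 50 ms does not
#' count). It is computed here over a trailing window of `window_beats`
#' beats, emitted at every beat, and anchored at the window's last beat, so
#' the sample at a given time summarises only the minute or so *before* it —
#' the event-locked analysis relies on this: the sample at a nod excludes the
#' nod, the sample one lag later contains it.
#'
#' Only differences between beats that are adjacent in the original
#' recording are counted; where [reject_artifacts()] removed beats, the pair
#' spanning the gap is dropped from both numerator and denominator. The
#' denominator is therefore the number of true adjacent pairs fully inside
#' the window (at most `window_beats - 1`).
#'
#' @param rri an [rri_series()].
#' @param window_beats number of beats per window (default 100, roughly one
#'   minute at typical resting heart rates); must be at least 2.
#' @return A `metric_series` data frame with columns `t` (anchor beat time,
#'   seconds), `value` (proportion in `[0, 1]`, `NA` where invalid) and
#'   `valid` (`FALSE` until a full window fits inside the recording, or when
#'   a window has no countable pair). Attributes: `metric = "pnn50"`,
#'   `window`, `session_id`.
#' @export
#' @examples
#' x <- rri_series(c(800, 860, 870, 930, 935))
#' compute_pnn50(x, window_beats = 5)$value  # 2 of 4 diffs exceed 50 ms
compute_pnn50 <- function(rri, window_beats = 100L) {
  stopifnot(inherits(rri, "rri_series"))
  w <- as.integer(window_beats)
  if (is.na(w) || w < 2L) {
    stop("invalid `window_beats`: must be an integer >= 2", call. = FALSE)
  }
  n <- nrow(rri)
  value <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  if (n >= w) {
    d <- abs(diff(rri$rri))
    pair_ok <- !rri$gap_before[-1L]          # pair (k-1, k) is a true pair
    hit <- as.numeric(d > 50 & pair_ok)
    cnt <- c(0, cumsum(hit))                 # hits among pairs 1..k-1
    den <- c(0, cumsum(as.numeric(pair_ok)))
    k <- w:n
    num_k <- cnt[k] - cnt[k - w + 1L]        # pairs inside window k-w+1..k
    den_k <- den[k] - den[k - w + 1L]
    ok <- den_k > 0
    value[k[ok]] <- num_k[ok] / den_k[ok]
    valid[k] <- ok
  } else if (n > 0L) {
    warning(sprintf("series shorter than window (%d < %d): no valid samples",
                    n, w), call. = FALSE)
  }
  metric_series(t = rri$t, value = value, valid = valid, metric = "pnn50",
                window = list(window_beats = w),
                session_id = session_id(rri))
}

# internal constructor shared by the metric computations
metric_series <- function(t, value, valid, metric, window, session_id) {
  out <- data.frame(t = t, value = value, valid = valid)
  attr(out, "metric") <- metric
  attr(out, "window") <- window
  attr(out, "session_id") <- session_id
  class(out) <- c("metric_series", "data.frame")
  out
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s, session '%s': %d samples (%d valid)\n",
              attr(x, "metric"), attr(x, "session_id"), nrow(x),
              sum(x$valid)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Remove implausible beats from an RR-interval series
#'
#' Screens a recording for artefacts before HRV analysis: beats whose
#' interval falls outside physiological bounds, or that jump by more than a
#' fraction `max_rel_jump` relative to the previous *accepted* beat, are
#' removed. The beat following a removal is flagged (`gap_before`) so that
#' downstream pNN50 windows do not count the spurious difference across the
#' gap. No beat is dropped silently: the removals are returned as a report.
#'
#' @param rri an [rri_series()].
#' @param max_rel_jump maximum allowed relative change between consecutive
#'   accepted intervals (default 0.3).
#' @param bounds_ms length-2 numeric: acceptable RRI range in ms.
#' @return The filtered [rri_series()], with attribute `rejections`: a data
#'   frame of the removed beats (`index` in the input, `t`, `rri`, `reason`).
#' @export
reject_artifacts <- function(rri, max_rel_jump = 0.3,
                             bounds_ms = c(300, 2000)) {
  stopifnot(inherits(rri, "rri_series"))
  n <- nrow(rri)
  keep <- logical(n)
  reason <- character(0); idx <- integer(0)
  last <- NA_real_
  for (k in seq_len(n)) {
    v <- rri$rri[k]
    if (v < bounds_ms[1L] || v > bounds_ms[2L]) {
      idx <- c(idx, k); reason <- c(reason, "out_of_bounds")
    } else if (!is.na(last) && abs(v - last) / last > max_rel_jump) {
      idx <- c(idx, k); reason <- c(reason, "relative_jump")
    } else {
      keep[k] <- TRUE
      last <- v
    }
  }
  gap <- rri$gap_before
  removed_before <- c(FALSE, !keep[-n])  # was the preceding input beat removed?
  gap_new <- (gap | removed_before)[keep]
  out <- rri_series(rri$rri[keep], t = rri$t[keep],
                    session_id = session_id(rri), gap_before = gap_new)
  attr(out, "rejections") <- data.frame(
    index = idx, t = rri$t[idx], rri = rri$rri[idx], reason = reason)
  if (length(idx)) {
    warning(sprintf("session %s: removed %d artefactual beat(s)",
                    session_id(rri), length(idx)), call. = FALSE)
  }
  out
}
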