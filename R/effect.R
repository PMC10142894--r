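#' Configuration for the event-locked effect statistic
#'
#' @param t0_s lag in seconds between the two pNN50 anchor points (default
#'   60: the pNN50 window is about a minute, so the later anchor's window
#'   covers the minute following the event while the earlier anchor's window
#'   excludes it).
#' @param baseline_guard_s seconds before a baseline probe that must be
#'   nod-free (default equal to `t0_s`, so that neither of the probe's two
#'   anchor windows can contain a nod).
#' @param sleep_policy `"include"` (default) keeps samples whose span
#'   overlaps a sleep annotation; `"exclude"` drops them.
#' @param baseline_stride_s optional spacing in seconds between baseline
#'   probes. `NULL` (default) probes at every valid metric sample; a stride
#'   of the order of the window length gives approximately independent
#'   baseline values, which matters when they are fed into a rank test.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(t0_s = 60, baseline_guard_s = t0_s,
                          sleep_policy = c("include", "exclude"),
                          baseline_stride_s = NULL) {
  sleep_policy <- match.arg(sleep_policy)
  if (t0_s <= 0) stop("invalid `t0_s`: must be > 0", call. = FALSE)
  if (baseline_guard_s < 0) {
    stop("invalid `baseline_guard_s`: must be >= 0", call. = FALSE)
  }
  structure(list(t0_s = t0_s, baseline_guard_s = baseline_guard_s,
                 sleep_policy = sleep_policy,
                 baseline_stride_s = baseline_stride_s),
            class = "effect_config")
}

#' Session-wide pNN50 trend
#'
#' Ordinary-least-squares slope of the metric against time over all valid
#' samples of one continuous recording, in units per second. This is the
#' participant's underlying drift in parasympathetic tone (for instance a
#' slow rise with sleepiness), which the per-event statistic subtracts so
#' that the event-locked change is measured relative to the session's own
#' tendency.
#'
#' @param metric a `metric_series` (normally pNN50).
#' @return Slope in metric units per second.
#' @export
global_trend <- function(metric) {
  stopifnot(inherits(metric, "metric_series"))
  ok <- metric$valid & !is.na(metric$value)
  if (sum(ok) < 2L) {
    stop("global trend needs at least 2 valid metric samples", call. = FALSE)
  }
  t <- metric$t[ok]; v <- metric$value[ok]
  tc <- t - mean(t)
  sum(tc * (v - mean(v))) / sum(tc^2)
}

# latest valid sample at or before each x (last-observation anchoring, no
# interpolation); value and its anchor time, NA when x precedes the first
# valid sample
metric_anchor <- function(metric, x) {
  ok <- metric$valid & !is.na(metric$value)
  tv <- metric$t[ok]; vv <- metric$value[ok]
  i <- findInterval(x, tv)
  value <- t_a <- rep(NA_real_, length(x))
  value[i > 0L] <- vv[i[i > 0L]]
  t_a[i > 0L] <- tv[i[i > 0L]]
  list(t = t_a, value = value)
}

metric_at <- function(metric, x) metric_anchor(metric, x)$value

#' Event-locked slope at one anchor time
#'
#' The slope of pNN50 from the event to one lag later:
#' `Ns = (pNN50(t + t0) - pNN50(t)) / elapsed`, where `pNN50(x)` is the
#' latest valid sample at or before `x` and `elapsed` is the actual time
#' between the two anchored samples. Anchors fall on beat times, so
#' `elapsed` equals `t0` whenever the anchors align with the nominal times
#' and differs from it by at most one beat otherwise; using the actual
#' spacing keeps the statistic an unbiased slope (a series that is exactly
#' linear with slope `b` yields `Ns = b` at every anchor, on any beat grid).
#' Because the metric windows trail their anchor, the sample at `t`
#' summarises the minute before the event and the sample at `t + t0` the
#' minute after it.
#'
#' @param metric a `metric_series`.
#' @param t anchor (event) time in seconds.
#' @param t0_s lag in seconds.
#' @return Slope per second, or `NA` when either anchor is unresolvable
#'   (before the first valid sample or after the last).
#' @export
nod_slope <- function(metric, t, t0_s = 60) {
  stopifnot(inherits(metric, "metric_series"))
  ok <- metric$valid & !is.na(metric$value)
  if (!any(ok)) return(rep(NA_real_, length(t)))
  t_max <- max(metric$t[ok])
  a0 <- metric_anchor(metric, t)
  a1 <- metric_anchor(metric, t + t0_s)
  elapsed <- a1$t - a0$t
  out <- (a1$value - a0$value) / elapsed
  out[t + t0_s > t_max] <- NA_real_
  out[!is.na(elapsed) & elapsed == 0] <- NA_real_
  out
}

#' Per-nod effect values for one recording
#'
#' For every includable nod at time `t`, computes the event-locked slope
#' `Ns` over the following `t0_s` seconds, subtracts the session trend
#' `Nall` ([global_trend()]), and reports the effect `n = Ns - Nall` in
#' units per second. A negative `n` means pNN50 fell faster than the
#' session's own trend after the event — read as increased arousal.
#'
#' Nods are excluded (never silently) when an anchor cannot be resolved:
#' before the first valid metric sample, or closer than `t0_s` to the end of
#' the recording; with `sleep_policy = "exclude"`, also when
#' `[t, t + t0_s]` overlaps a sleep span. The exclusions, with reasons, are
#' attached as attribute `exclusions`, so that every nod in the track is
#' accounted for.
#'
#' @param metric a pNN50 `metric_series`.
#' @param events an [event_track()] from the same recording.
#' @param cfg an [effect_config()].
#' @return A data frame of class `effect_samples` with columns
#'   `session_id`, `condition`, `half`, `kind` (`"nod"`), `anchor_t`, `ns`,
#'   `n_all`, `n`; attributes `t0_s`, `exclusions`.
#' @export
nodding_effects <- function(metric, events, cfg = effect_config()) {
  stopifnot(inherits(events, "event_track"), inherits(cfg, "effect_config"))
  build_effects(metric, events, cfg, probes = events$nods, kind = "nod",
                guard = NULL)
}

#' Matched non-nod baseline effect values
#'
#' Applies the identical statistic at probe times where the participant did
#' not nod: every valid metric sample time `s` (or a strided subset) such
#' that no nod lies in `[s - baseline_guard_s, s + t0_s]`, so neither anchor
#' window can overlap a nod. The resulting values estimate the trend of
#' pNN50 in the nod-free intervals and form the reference distribution for
#' the three-condition comparison.
#'
#' @inheritParams nodding_effects
#' @return An `effect_samples` data frame with `kind = "baseline"`.
#' @export
baseline_effects <- function(metric, events, cfg = effect_config()) {
  stopifnot(inherits(events, "event_track"), inherits(cfg, "effect_config"))
  ok <- metric$valid & !is.na(metric$value)
  probes <- metric$t[ok]
  if (!is.null(cfg$baseline_stride_s) && length(probes)) {
    keep <- logical(length(probes))
    next_t <- probes[1L]
    for (i in seq_along(probes)) {
      if (probes[i] >= next_t) {
        keep[i] <- TRUE
        next_t <- probes[i] + cfg$baseline_stride_s
      }
    }
    probes <- probes[keep]
  }
  build_effects(metric, events, cfg, probes = probes, kind = "baseline",
                guard = cfg$baseline_guard_s)
}

build_effects <- function(metric, events, cfg, probes, kind, guard) {
  stopifnot(inherits(metric, "metric_series"))
  ok <- metric$valid & !is.na(metric$value)
  n_all <- if (sum(ok) >= 2L) global_trend(metric) else NA_real_
  t_min <- if (any(ok)) min(metric$t[ok]) else Inf
  t_max <- if (any(ok)) max(metric$t[ok]) else -Inf

  excl_t <- numeric(); excl_why <- character()
  drop <- function(ts, why) {
    excl_t <<- c(excl_t, ts)
    excl_why <<- c(excl_why, rep(why, length(ts)))
  }
  if (is.na(n_all)) {
    drop(probes, "insufficient_metric_samples")
    probes <- numeric()
  }
  if (!is.null(guard) && length(probes) && length(events$nods)) {
    # a nod in [s - guard, s + t0] disqualifies probe s
    hi <- findInterval(probes + cfg$t0_s, events$nods)
    lo <- findInterval(probes - guard, events$nods,
                       left.open = TRUE)  # nods strictly below s - guard
    bad <- hi > lo
    drop(probes[bad], "nod_within_guard")
    probes <- probes[!bad]
  }
  if (length(probes)) {
    bad <- probes < t_min
    drop(probes[bad], "before_first_valid_sample")
    probes <- probes[!bad]
  }
  if (length(probes)) {
    bad <- probes + cfg$t0_s > t_max
    drop(probes[bad], "beyond_last_valid_sample")
    probes <- probes[!bad]
  }
  if (cfg$sleep_policy == "exclude" && length(probes) && nrow(events$sleep)) {
    sl <- events$sleep
    # overlap of [s, s + t0] with any sleep span
    bad <- vapply(probes, function(s) {
      any(s <= sl$end & s + cfg$t0_s >= sl$start)
    }, logical(1L))
    drop(probes[bad], "sleep_overlap")
    probes <- probes[!bad]
  }
  ns <- nod_slope(metric, probes, cfg$t0_s)
  if (anyNA(ns)) {  # defensive: anchors already screened above
    bad <- is.na(ns)
    drop(probes[bad], "unresolvable_anchor")
    probes <- probes[!bad]; ns <- ns[!bad]
  }
  out <- data.frame(
    session_id = rep(events$session_id, length(probes)),
    condition = rep(events$condition, length(probes)),
    half = rep(events$half, length(probes)),
    kind = rep(kind, length(probes)),
    anchor_t = probes, ns = ns,
    n_all = rep(n_all, length(probes)),
    n = ns - n_all)
  attr(out, "t0_s") <- cfg$t0_s
  attr(out, "exclusions") <- data.frame(anchor_t = excl_t, reason = excl_why)
  class(out) <- c("effect_samples", "data.frame")
  if (!nrow(out)) {
    warning(sprintf("session %s: no includable %s probes",
                    events$session_id, kind), call. = FALSE)
  }
  out
}
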