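#' Parameters for a synthetic study recording
#'
#' Collects the generative settings for one synthetic RR-interval recording
#' with annotated nod events. The generator models the tachogram as
#' `RRI(t) = mean + drift(t) + LF sinusoid + HF sinusoid + AR(1) noise`, with
#' the AR(1) innovation scale multiplied by `1 + effect_delta` for
#' `effect_duration_s` seconds after each nod onset. Because pNN50 is driven
#' by successive-difference variability, `effect_delta` directly controls the
#' sign and size of the event-locked pNN50 response, giving downstream
#' analyses a known ground truth.
#'
#' @param duration_s recording length in seconds (a lecture half; the study
#'   design is a 30 min first half and a 60 min second half).
#' @param mean_rri_ms baseline inter-beat interval in ms.
#' @param drift baseline slope in ms per second: either a scalar (constant
#'   slope) or a data frame with columns `t` (knot times, seconds, first
#'   must be 0) and `slope` (ms/s applying from that knot), giving a
#'   piecewise-linear baseline.
#' @param sd_noise_ms innovation standard deviation of the AR(1) short-term
#'   variability, in ms.
#' @param ar_coeff beat-to-beat autocorrelation of the noise, in `[0, 1)`.
#' @param lf_amp_ms,lf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   low-frequency (Mayer-wave range) sinusoidal modulation.
#' @param hf_amp_ms,hf_freq_hz amplitude and frequency of the high-frequency
#'   (respiratory range) modulation. Frequencies must lie in (0, 0.5) Hz.
#' @param condition experimental condition label for the recording.
#' @param nod_rate_per_min spontaneous nod rate (events/min) for the
#'   non-forced conditions; nod times are a homogeneous Poisson process.
#' @param cue_times explicit cue times in seconds for the forced condition;
#'   when supplied, nods occur exactly at the cues.
#' @param effect_delta fractional change of the innovation scale inside the
#'   post-nod effect window, in `[-1, 1]`. Negative values suppress
#'   successive-difference variability (lower pNN50, i.e. arousal).
#' @param effect_duration_s length of the post-nod effect window in seconds.
#' @param sleep_intervals data frame of `start`, `end` (seconds) spans to be
#'   labelled as sleep, or `NULL`.
#' @param half which lecture half this recording represents.
#' @param seed integer seed making the recording reproducible.
#'
#' @return A list of class `sim_params`.
#' @seealso [simulate_session()], [simulate_cohort()]
#' @export
sim_params <- function(duration_s = 3600, mean_rri_ms = 850, drift = 0,
                       sd_noise_ms = 30, ar_coeff = 0.4,
                       lf_amp_ms = 10, lf_freq_hz = 0.1,
                       hf_amp_ms = 10, hf_freq_hz = 0.25,
                       condition = c("no_nodding_video",
                                     "with_video_not_forced",
                                     "with_video_forced"),
                       nod_rate_per_min = 0.4, cue_times = NULL,
                       effect_delta = 0, effect_duration_s = 60,
                       sleep_intervals = NULL,
                       half = c("second", "first"), seed = 1L) {
  condition <- match.arg(condition)
  half <- match.arg(half)
  if (!is.numeric(duration_s) || duration_s < 0) {
    stop("invalid `duration_s`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(sd_noise_ms) || sd_noise_ms < 0) {
    stop("invalid `sd_noise_ms`: must be >= 0", call. = FALSE)
  }
  if (!is.numeric(ar_coeff) || ar_coeff < 0 || ar_coeff >= 1) {
    stop("invalid `ar_coeff`: must be in [0, 1)", call. = FALSE)
  }
  if (effect_duration_s <= 0) {
    stop("invalid `effect_duration_s`: must be > 0", call. = FALSE)
  }
  if (abs(effect_delta) > 1) {
    stop("invalid `effect_delta`: must be in [-1, 1]", call. = FALSE)
  }
  for (f in c("lf_freq_hz", "hf_freq_hz")) {
    v <- get(f)
    if (v <= 0 || v >= 0.5) {
      stop(sprintf("invalid `%s`: must be in (0, 0.5) Hz", f), call. = FALSE)
    }
  }
  if (lf_amp_ms < 0 || hf_amp_ms < 0) {
    stop("invalid modulation amplitude: must be >= 0", call. = FALSE)
  }
  if (nod_rate_per_min < 0) {
    stop("invalid `nod_rate_per_min`: must be >= 0", call. = FALSE)
  }
  if (is.numeric(drift)) {
    drift <- data.frame(t = 0, slope = drift)
  } else {
    drift <- as.data.frame(drift)[, c("t", "slope")]
    if (!nrow(drift) || drift$t[1L] != 0 || is.unsorted(drift$t, strictly = TRUE)) {
      stop("invalid `drift`: knot times must start at 0 and increase", call. = FALSE)
    }
  }
  structure(
    list(duration_s = duration_s, mean_rri_ms = mean_rri_ms, drift = drift,
         sd_noise_ms = sd_noise_ms, ar_coeff = ar_coeff,
         lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
         hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
         condition = condition, nod_rate_per_min = nod_rate_per_min,
         cue_times = cue_times, effect_delta = effect_delta,
         effect_duration_s = effect_duration_s,
         sleep_intervals = sleep_intervals, half = half,
         seed = as.integer(seed)),
    class = "sim_params")
}

#' Simulate one synthetic recording
#'
#' Generates nod events first (Poisson for non-forced conditions, the cue
#' times for the forced condition), then the RR-interval stream beat by beat.
#' Inside the union of the per-event effect windows
#' `[nod, nod + effect_duration_s)` the AR(1) innovation standard deviation
#' is `sd_noise_ms * (1 + effect_delta)`; overlapping windows are merged, not
#' stacked. Generated intervals are clamped to \[300, 2000\] ms and clamp
#' events counted. Deterministic given the seed in `params`.
#'
#' @param params a [sim_params()] object.
#' @return A list of class `sim_session` with elements `rri`
#'   ([rri_series()]), `events` ([event_track()]) and `truth` (the injected
#'   `effect_delta`, the per-event windows, the merged windows actually
#'   applied, and the clamp count).
#' @export
#' @examples
#' s <- simulate_session(sim_params(duration_s = 120, seed = 42))
#' s$rri
#' s$events
simulate_session <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  sid <- sprintf("sim-%s-%s-%d", p$condition, p$half, p$seed)

  nods <- if (p$condition == "with_video_forced" && !is.null(p$cue_times)) {
    sort(as.numeric(p$cue_times))
  } else if (!is.null(p$cue_times)) {
    sort(as.numeric(p$cue_times))
  } else {
    n_ev <- stats::rpois(1L, p$nod_rate_per_min / 60 * p$duration_s)
    sort(stats::runif(n_ev, 0, p$duration_s))
  }
  nods <- nods[nods >= 0 & nods <= p$duration_s]

  windows <- data.frame(start = nods, end = nods + p$effect_duration_s)
  merged <- normalize_intervals(windows$start, windows$end)

  dk <- p$drift
  offsets <- c(0, cumsum(dk$slope[-nrow(dk)] * diff(dk$t)))
  gen <- generate_rri_cpp(p$duration_s, p$mean_rri_ms,
                          dk$t, dk$slope, offsets,
                          p$lf_amp_ms, p$lf_freq_hz,
                          p$hf_amp_ms, p$hf_freq_hz,
                          p$sd_noise_ms, p$ar_coeff,
                          merged$start, merged$end,
                          p$effect_delta, 300, 2000)

  rri <- rri_series(gen$rri, t = gen$t, session_id = sid)
  events <- event_track(nods = nods, sleep = p$sleep_intervals,
                        condition = p$condition, half = p$half,
                        session_id = sid)
  if (gen$n_clamped > 0) {
    message(sprintf("session %s: %d RRI value(s) clamped to [300, 2000] ms",
                    sid, gen$n_clamped))
  }
  structure(
    list(rri = rri, events = events,
         truth = list(effect_delta = p$effect_delta,
                      windows = windows, merged_windows = merged,
                      n_clamped = gen$n_clamped),
         params = p),
    class = "sim_session")
}

#' Simulate a three-condition cohort
#'
#' Produces `n_per_group[i]` recordings for each condition template, with
#' per-session seeds derived reproducibly from the master seed so that
#' sessions are mutually independent but the whole cohort is reproducible.
#'
#' @param n_per_group integer vector of length 3: sessions per condition, in
#'   the order of `group_params`.
#' @param group_params list of three [sim_params()] templates (one per
#'   condition); each template's `seed` is overridden per session.
#' @param seed master integer seed.
#' @return List of `sim_session` objects, conditions interleaved by group.
#' @export
simulate_cohort <- function(n_per_group, group_params, seed = 1L) {
  if (length(n_per_group) != length(group_params)) {
    stop("`n_per_group` and `group_params` lengths differ", call. = FALSE)
  }
  if (any(n_per_group < 1)) {
    stop("invalid `n_per_group`: every group needs at least one session",
         call. = FALSE)
  }
  set.seed(seed)
  total <- sum(n_per_group)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  out <- vector("list", total)
  i <- 0L
  for (g in seq_along(group_params)) {
    tmpl <- group_params[[g]]
    for (j in seq_len(n_per_group[g])) {
      i <- i + 1L
      tmpl$seed <- seeds[i]
      out[[i]] <- simulate_session(tmpl)
    }
  }
  out
}
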