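#' Lomb-Scargle periodogram of an unevenly sampled series
#'
#' Classic least-squares spectral estimate for data on an irregular time
#' grid, as needed for the RRI tachogram, whose natural sampling times are
#' the beat times themselves. The series is mean-centred; the time-offset
#' `tau` makes the estimate invariant to time translation.
#'
#' @param t sample times (seconds).
#' @param y sample values.
#' @param freq frequencies (Hz) at which to evaluate.
#' @return Numeric vector of spectral power at `freq` (same units as
#'   `var(y)` per frequency bin; only relative band powers are used here).
#' @export
lomb_scargle <- function(t, y, freq) {
  stopifnot(length(t) == length(y), length(t) >= 2L)
  y <- y - mean(y)
  omega <- 2 * pi * freq
  # outer(omega, t) is nfreq x nbeats; fine for the window sizes used here
  wt <- outer(omega, t)
  s2 <- rowSums(sin(2 * wt)); c2 <- rowSums(cos(2 * wt))
  tau <- atan2(s2, c2) / (2 * omega)
  wtt <- wt - omega * tau
  cwt <- cos(wtt); swt <- sin(wtt)
  yc <- as.numeric(cwt %*% y); ys <- as.numeric(swt %*% y)
  cc <- rowSums(cwt^2); ss <- rowSums(swt^2)
  p <- 0.5 * (yc^2 / cc + ys^2 / ss)
  p[!is.finite(p)] <- 0
  p
}

#' Sliding-window LF/HF ratio series
#'
#' Estimates the ratio of low-frequency to high-frequency spectral power of
#' the RRI tachogram over a trailing window (default the past two minutes),
#' stepped along the recording. LF/HF rises with sympathetic activation. The
#' spectrum is estimated on the uneven beat-time grid with the Lomb-Scargle
#' periodogram (default) or, alternatively, after cubic-spline resampling to
#' an even 4 Hz grid followed by a smoothed periodogram; both integrate the
#' same bands.
#'
#' A window is invalid (value `NA`, `valid = FALSE`) when it holds fewer
#' than `min_beats` beats, when the tachogram is degenerate (constant), or
#' when the HF power is below machine tolerance.
#'
#' @param rri an [rri_series()].
#' @param window_s trailing window length in seconds (default 120).
#' @param step_s spacing of window anchors in seconds (default 1).
#' @param lf_band,hf_band frequency bands in Hz; defaults are the
#'   conventional 0.04-0.15 and 0.15-0.40 Hz.
#' @param method `"lombscargle"` or `"welch"`.
#' @param min_beats minimum beats required in a window (default 30).
#' @return A `metric_series` with columns `t` (anchor = window end), `value`
#'   (LF/HF, dimensionless, `NA` where invalid) and `valid`.
#' @export
compute_lf_hf <- function(rri, window_s = 120, step_s = 1,
                          lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.40),
                          method = c("lombscargle", "welch"),
                          min_beats = 30L) {
  stopifnot(inherits(rri, "rri_series"))
  method <- match.arg(method)
  n <- nrow(rri)
  t_last <- if (n) rri$t[n] else 0
  t_first <- if (n) rri$t[1L] else 0
  anchors <- if (n && t_last - t_first >= window_s) {
    seq(t_first + window_s, t_last, by = step_s)
  } else numeric()
  value <- rep(NA_real_, length(anchors))
  valid <- rep(FALSE, length(anchors))
  # oversampled frequency grid spanning both bands
  df <- 1 / (4 * window_s)
  freq <- seq(df, max(lf_band[2L], hf_band[2L]), by = df)
  in_lf <- freq > lf_band[1L] & freq <= lf_band[2L]
  in_hf <- freq > hf_band[1L] & freq <= hf_band[2L]
  for (i in seq_along(anchors)) {
    a <- anchors[i]
    sel <- rri$t > a - window_s & rri$t <= a
    if (sum(sel) < min_beats) next
    tt <- rri$t[sel]; yy <- rri$rri[sel]
    if (stats::sd(yy) < .Machine$double.eps^0.5) next
    pw <- if (method == "lombscargle") {
      lomb_scargle(tt, yy, freq)
    } else {
      welch_power(tt, yy, freq)
    }
    lf <- sum(pw[in_lf]); hf <- sum(pw[in_hf])
    if (hf <= .Machine$double.eps * sum(pw)) next
    value[i] <- lf / hf
    valid[i] <- TRUE
  }
  metric_series(t = anchors, value = value, valid = valid, metric = "lf_hf",
                window = list(window_s = window_s, step_s = step_s,
                              lf_band = lf_band, hf_band = hf_band,
                              method = method),
                session_id = session_id(rri))
}

# Spectral power at `freq` from cubic-spline resampling to 4 Hz followed by
# a tapered, smoothed periodogram; values interpolated onto `freq`.
welch_power <- function(tt, yy, freq, fs = 4) {
  grid <- seq(tt[1L], tt[length(tt)], by = 1 / fs)
  y4 <- stats::spline(tt, yy, xout = grid)$y
  sp <- stats::spec.pgram(stats::ts(y4, frequency = fs),
                          spans = c(5, 5), taper = 0.1, detrend = TRUE,
                          plot = FALSE)
  stats::approx(sp$freq, sp$spec, xout = freq, rule = 2)$y
}
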