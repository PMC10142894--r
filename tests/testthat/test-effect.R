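mk_metric <- function(t, value) {
  nodeffect:::metric_series(t = t, value = value,
                            valid = rep(TRUE, length(t)), metric = "pnn50",
                            window = list(window_beats = 100L),
                            session_id = "fx")
}

test_that("global trend recovers flat and exactly linear series and the hand OLS fixture", {
  t <- seq(0, 600, by = 5)
  expect_equal(global_trend(mk_metric(t, rep(0.3, length(t)))), 0)
  expect_equal(global_trend(mk_metric(t, 0.1 + 2e-4 * t)), 2e-4,
               tolerance = 1e-12)

  # closed-form OLS oracle on the 5-point fixture
  tf <- c(0, 60, 120, 180, 240)
  vf <- c(0.30, 0.32, 0.31, 0.35, 0.34)
  beta <- sum((tf - mean(tf)) * (vf - mean(vf))) / sum((tf - mean(tf))^2)
  expect_equal(global_trend(mk_metric(tf, vf)), beta)
  expect_equal(beta, 6.6 / 36000)

  expect_error(global_trend(mk_metric(10, 0.5)), "at least 2")
})

test_that("nod slope is the lagged difference over t0 with last-observation anchoring", {
  m <- mk_metric(c(100, 160), c(0.40, 0.34))
  expect_equal(nod_slope(m, 100, 60), -0.001)

  # linear series: slope b at every interior anchor
  t <- seq(0, 500, by = 1)
  lin <- mk_metric(t, 0.2 + 5e-4 * t)
  expect_equal(nod_slope(lin, c(50, 123, 400), 60), rep(5e-4, 3),
               tolerance = 1e-10)

  # anchoring uses the latest sample at or before x, not interpolation
  m2 <- mk_metric(c(0, 10, 20, 80, 90), c(0.1, 0.2, 0.3, 0.5, 0.6))
  # anchors at t=10 and t=20; slope over the actual anchor spacing
  expect_equal(nod_slope(m2, 15, 60), (0.3 - 0.2) / (20 - 10))

  # too close to the end of the recording -> NA (excluded downstream)
  expect_true(is.na(nod_slope(lin, 460, 60)))
  expect_true(is.na(nod_slope(lin, -10, 60)))
})

test_that("nodding effect is zero on linear series and invariant to added ramps", {
  t <- seq(0, 900, by = 0.8)
  set.seed(12)
  v <- 0.3 + 0.1 * sin(t / 80) + rnorm(length(t), 0, 0.01)
  ev <- event_track(nods = c(100, 250, 400, 700),
                    condition = "with_video_not_forced", session_id = "fx")
  cfg <- effect_config()

  lin <- mk_metric(t, 0.1 + 3e-4 * t)
  e0 <- nodding_effects(lin, ev, cfg)
  expect_equal(nrow(e0), 4L)
  expect_true(all(abs(e0$n) < 1e-12))
  expect_equal(e0$n, e0$ns - e0$n_all)

  # adding a global ramp c*t changes Ns and Nall equally, never n
  base <- nodding_effects(mk_metric(t, v), ev, cfg)
  ramped <- nodding_effects(mk_metric(t, v + 2e-3 * t), ev, cfg)
  expect_equal(ramped$n, base$n, tolerance = 1e-10)
  # and the whole statistic is time-translation invariant
  moved <- nodding_effects(mk_metric(t + 5000, v),
                           event_track(nods = ev$nods + 5000,
                                       condition = ev$condition,
                                       session_id = "fx"), cfg)
  expect_equal(moved$n, base$n, tolerance = 1e-10)
})

test_that("every nod is accounted for: effects plus logged exclusions", {
  t <- seq(60, 600, by = 0.8)
  set.seed(3)
  m <- mk_metric(t, runif(length(t), 0.2, 0.4))
  ev <- event_track(nods = c(10, 100, 300, 560, 590),
                    condition = "with_video_not_forced", session_id = "fx")
  e <- nodding_effects(m, ev, effect_config())
  excl <- attr(e, "exclusions")
  expect_identical(nrow(e) + nrow(excl), length(ev$nods))
  expect_setdiff <- setdiff(excl$reason,
                            c("before_first_valid_sample",
                              "beyond_last_valid_sample"))
  expect_length(expect_setdiff, 0)
  # 10 s precedes the first valid sample; 560 and 590 run past the end
  expect_equal(sort(excl$anchor_t), c(10, 560, 590))
})

test_that("baseline effects equal the per-probe statistic and respect the guard", {
  t <- seq(0, 800, by = 1)
  set.seed(9)
  v <- 0.3 + cumsum(rnorm(length(t), 0, 0.002))
  m <- mk_metric(t, v)
  ev <- event_track(nods = c(200, 450), condition = "with_video_not_forced",
                    session_id = "fx")
  cfg <- effect_config(t0_s = 60, baseline_guard_s = 60)
  b <- baseline_effects(m, ev, cfg)
  expect_gt(nrow(b), 100)
  # no probe may have a nod within [s - guard, s + t0]
  for (nod in ev$nods) {
    expect_true(all(b$anchor_t < nod - 60 | b$anchor_t > nod + 60))
  }
  # construction equivalence: same value as calling the nod statistic there
  n_all <- global_trend(m)
  oracle <- nod_slope(m, b$anchor_t, 60) - n_all
  expect_equal(b$n, oracle, tolerance = 1e-12)

  # a nod-free session turns every eligible interior sample into a probe
  free <- baseline_effects(m, event_track(condition = "no_nodding_video",
                                          session_id = "fx"), cfg)
  expect_identical(nrow(free), sum(t + 60 <= max(t)))
  # exactly linear series: all baseline values vanish
  linb <- baseline_effects(mk_metric(t, 0.1 + 1e-4 * t),
                           event_track(condition = "no_nodding_video",
                                       session_id = "fx"), cfg)
  expect_true(all(abs(linb$n) < 1e-12))
})

test_that("stride and sleep policy thin the baseline probe set", {
  t <- seq(0, 800, by = 1)
  m <- mk_metric(t, 0.2 + 1e-4 * t)
  ev <- event_track(nods = numeric(),
                    sleep = data.frame(start = 300, end = 400),
                    condition = "no_nodding_video", session_id = "fx")
  b60 <- baseline_effects(m, ev, effect_config(baseline_stride_s = 60))
  expect_true(all(diff(b60$anchor_t) >= 60))
  asleep <- baseline_effects(m, ev, effect_config(sleep_policy = "exclude"))
  # [s, s+60] must not touch the 300-400 s sleep span
  expect_true(all(asleep$anchor_t + 60 < 300 | asleep$anchor_t > 400))
})
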