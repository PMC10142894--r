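test_that("pNN50 matches hand-enumerated and analytic cases", {
  x <- rri_series(c(800, 860, 870, 930, 935))
  p <- compute_pnn50(x, window_beats = 5)
  # diffs 60, 10, 60, 5 -> two of four exceed 50 ms
  expect_equal(p$value[5], 0.5)
  expect_identical(p$valid, c(rep(FALSE, 4), TRUE))

  const <- compute_pnn50(rri_series(rep(700, 150)))
  expect_true(all(const$value[const$valid] == 0))

  # strict inequality: differences of exactly 50 ms never count
  exact50 <- rri_series(rep(c(800, 850), 60))
  p50 <- compute_pnn50(exact50, window_beats = 20)
  expect_true(all(p50$value[p50$valid] == 0))

  expect_error(compute_pnn50(x, window_beats = 1), "window_beats")
  expect_warning(compute_pnn50(rri_series(rep(800, 5)), window_beats = 10),
                 "shorter")
})

test_that("sliding pNN50 equals the brute-force recompute on random series", {
  set.seed(101)
  for (rep in 1:25) {
    w <- sample(2:100, 1)
    x <- random_rri(sample(w:(w + 150), 1))
    p <- compute_pnn50(x, window_beats = w)
    expect_identical(p$value, brute_pnn50(x$rri, w))
  }
})

test_that("pNN50 is invariant to RRI offsets and time translation, monotone in diffs", {
  set.seed(7)
  x <- random_rri(200)
  p <- compute_pnn50(x, window_beats = 50)
  shifted <- rri_series(x$rri + 200, t = x$t + 1234)
  p2 <- compute_pnn50(shifted, window_beats = 50)
  expect_equal(p2$value, p$value)
  expect_equal(p2$t, p$t + 1234)

  # inflating all successive differences never lowers pNN50
  infl <- x$rri[1] + cumsum(c(0, diff(x$rri) * 1.8))
  p3 <- compute_pnn50(rri_series(infl - min(infl) + 400, t = x$t), 50)
  expect_true(all(p3$value[p3$valid] >= p$value[p$valid]))
})

test_that("artifact rejection removes planted spikes and flags gaps", {
  clean <- rri_series(rep(800, 50))
  out <- reject_artifacts(clean)
  expect_identical(out$rri, clean$rri)
  expect_identical(nrow(attr(out, "rejections")), 0L)

  spiked <- rri_series(c(rep(800, 20), 150, rep(800, 20)))
  expect_warning(filt <- reject_artifacts(spiked), "1 artefactual")
  rej <- attr(filt, "rejections")
  expect_equal(rej$index, 21L)
  expect_equal(rej$reason, "out_of_bounds")
  expect_true(filt$gap_before[21])  # the beat after the removal

  # pNN50 never counts the difference across the gap: still all zero
  p <- compute_pnn50(filt, window_beats = 10)
  expect_true(all(p$value[p$valid] == 0))
  # and the brute-force oracle agrees under gaps
  set.seed(55)
  x <- suppressWarnings(reject_artifacts(rri_series(
    c(rnorm(60, 800, 40), 2500, rnorm(60, 800, 40), 100, rnorm(30, 800, 40)))))
  pg <- compute_pnn50(x, window_beats = 30)
  expect_identical(pg$value, brute_pnn50(x$rri, 30, x$gap_before))

  jump <- rri_series(c(rep(800, 10), 1200, rep(800, 10)))
  expect_warning(fj <- reject_artifacts(jump), "artefactual")
  expect_equal(attr(fj, "rejections")$reason, "relative_jump")

  allbad <- rri_series(rep(250, 5))
  expect_warning(fa <- reject_artifacts(allbad))
  expect_identical(nrow(fa), 0L)
  expect_identical(nrow(attr(fa, "rejections")), 5L)
})

test_that("LF/HF isolates single-sinusoid power into the right band", {
  lf_only <- simulate_session(sim_params(duration_s = 400, sd_noise_ms = 2,
                                         lf_amp_ms = 30, lf_freq_hz = 0.10,
                                         hf_amp_ms = 0, nod_rate_per_min = 0,
                                         seed = 21))
  m <- compute_lf_hf(lf_only$rri, step_s = 60)
  expect_true(all(m$value[m$valid] > 10))

  hf_only <- simulate_session(sim_params(duration_s = 400, sd_noise_ms = 2,
                                         lf_amp_ms = 0, hf_amp_ms = 30,
                                         hf_freq_hz = 0.30,
                                         nod_rate_per_min = 0, seed = 22))
  m2 <- compute_lf_hf(hf_only$rri, step_s = 60)
  expect_true(all(m2$value[m2$valid] < 1))

  # degenerate constant tachogram yields invalid samples, not errors
  const <- simulate_session(sim_params(duration_s = 300, sd_noise_ms = 0,
                                       lf_amp_ms = 0, hf_amp_ms = 0,
                                       nod_rate_per_min = 0, seed = 23))
  m3 <- compute_lf_hf(const$rri, step_s = 60)
  expect_true(all(!m3$valid))
  expect_true(all(is.na(m3$value)))
})

test_that("Lomb-Scargle and resampled-Welch LF/HF agree on stationary series", {
  s <- simulate_session(sim_params(duration_s = 600, sd_noise_ms = 20,
                                   ar_coeff = 0.3, lf_amp_ms = 15,
                                   hf_amp_ms = 15, nod_rate_per_min = 0,
                                   seed = 24))
  ls <- compute_lf_hf(s$rri, step_s = 30, method = "lombscargle")
  we <- compute_lf_hf(s$rri, step_s = 30, method = "welch")
  ok <- ls$valid & we$valid
  expect_gt(sum(ok), 10)
  ratio <- median(ls$value[ok]) / median(we$value[ok])
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})
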