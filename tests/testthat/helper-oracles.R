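# Independent brute-force oracles and small fixture builders shared by the
# test files. These deliberately avoid the package's own sliding-window or
# closed-form code paths.

# pNN50 by literal recomputation of every window: for anchor beat k, count
# |rri[j] - rri[j-1]| > 50 over the window's adjacent pairs.
brute_pnn50 <- function(rri, w, gap_before = rep(FALSE, length(rri))) {
  n <- length(rri)
  out <- rep(NA_real_, n)
  if (n < w) return(out)
  for (k in w:n) {
    idx <- (k - w + 1L):k
    num <- 0L; den <- 0L
    for (j in idx[-1L]) {
      if (gap_before[j]) next
      den <- den + 1L
      if (abs(rri[j] - rri[j - 1L]) > 50) num <- num + 1L
    }
    out[k] <- if (den > 0L) num / den else NA_real_
  }
  out
}

# Kruskal-Wallis H via direct evaluation of the textbook formula, written
# independently of the package (explicit rank construction via sorting).
brute_kw_h <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  o <- order(x)
  r <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- i
    while (j < N && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  sizes <- lengths(groups)
  stopcum <- cumsum(sizes)
  startcum <- c(1L, utils::head(stopcum, -1L) + 1L)
  Rsum <- mapply(function(a, b) sum(r[a:b]), startcum, stopcum)
  H0 <- 12 / (N * (N + 1)) * sum(Rsum^2 / sizes) - 3 * (N + 1)
  tie_sizes <- as.numeric(table(x))
  H0 / (1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N))
}

# Exact permutation p-value of H for small pooled samples: enumerate every
# assignment of the pooled values to the group sizes.
perm_kw_p <- function(groups) {
  x <- unlist(groups)
  sizes <- lengths(groups)
  N <- length(x)
  h_obs <- brute_kw_h(groups)
  idx_all <- seq_len(N)
  count <- 0L; total <- 0L
  for (c1 in utils::combn(idx_all, sizes[1L], simplify = FALSE)) {
    rest <- setdiff(idx_all, c1)
    for (c2 in utils::combn(rest, sizes[2L], simplify = FALSE)) {
      c3 <- setdiff(rest, c2)
      h <- brute_kw_h(list(x[c1], x[c2], x[c3]))
      total <- total + 1L
      if (h >= h_obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

cue_grid <- function(duration_s, step_s) {
  lo <- min(90, duration_s / 4)
  if (duration_s - lo < lo) return(numeric())
  seq(lo, duration_s - lo, by = step_s)
}

random_rri <- function(n, mean_ms = 800, sd_ms = 40) {
  rri_series(pmax(300, rnorm(n, mean_ms, sd_ms)))
}

# A small three-condition cohort template used by the recovery tests.
cohort_templates <- function(duration_s, sd_noise_ms = 30, ar = 0.4,
                             nod_rate = 2, cue_step_s = 30,
                             deltas = c(0, -0.3, 0.3)) {
  list(
    sim_params(duration_s = duration_s, condition = "no_nodding_video",
               sd_noise_ms = sd_noise_ms, ar_coeff = ar,
               nod_rate_per_min = 0, effect_delta = deltas[1L]),
    sim_params(duration_s = duration_s, condition = "with_video_not_forced",
               sd_noise_ms = sd_noise_ms, ar_coeff = ar,
               nod_rate_per_min = nod_rate, effect_delta = deltas[2L]),
    sim_params(duration_s = duration_s, condition = "with_video_forced",
               sd_noise_ms = sd_noise_ms, ar_coeff = ar,
               cue_times = cue_grid(duration_s, cue_step_s),
               effect_delta = deltas[3L]))
}

# Fixed-seed study configuration backing the golden-file regression test;
# regenerate the stored report with tools/make_golden.R after intentional
# changes.
golden_config <- function() {
  tmpl <- cohort_templates(duration_s = 420, nod_rate = 2, cue_step_s = 40,
                           deltas = c(0, -0.3, 0.3))
  sessions <- simulate_cohort(c(2, 2, 2), tmpl, seed = 424242)
  list(sessions = lapply(sessions, function(s) {
    list(rri = s$rri, events = s$events, condition = s$events$condition,
         half = s$events$half)
  }), baseline_stride_s = 60, seed = 424242)
}

# Pooled effect samples for a simulated cohort under one analysis config.
cohort_effects <- function(sessions, cfg) {
  do.call(rbind, lapply(sessions, function(s) {
    pnn <- compute_pnn50(s$rri)
    suppressWarnings(
      rbind(as.data.frame(nodding_effects(pnn, s$events, cfg)),
            as.data.frame(baseline_effects(pnn, s$events, cfg))))
  }))
}
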