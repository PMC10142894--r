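test_that("Kruskal-Wallis reproduces closed-form and brute-force values", {
  kw <- kruskal_wallis(list(1:3, 4:6, 7:9))
  expect_equal(kw$H, 7.2)
  expect_identical(kw$df, 2L)
  expect_equal(kw$p, pchisq(7.2, 2, lower.tail = FALSE))

  # tie-corrected H equals an independent direct-formula evaluation,
  # and the field-standard implementation, on tied fixtures
  fixtures <- list(
    list(c(1, 1, 2), c(2, 3, 3)),
    list(c(5, 5, 5, 7), c(5, 7, 8), c(8, 8, 9)),
    list(c(0.1, 0.2, 0.2, 0.2), c(0.2, 0.3), c(0.1, 0.3, 0.3)))
  for (g in fixtures) {
    expect_equal(kruskal_wallis(g)$H, brute_kw_h(g))
    ref <- stats::kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    expect_equal(kruskal_wallis(g)$H, unname(ref$statistic))
    expect_equal(kruskal_wallis(g)$p, unname(ref$p.value))
  }

  expect_error(kruskal_wallis(list(1:3)), "2 groups")
  expect_error(kruskal_wallis(list(c(2, 2), c(2, 2, 2))), "identical")
})

test_that("H is rank-based: invariant under strictly monotone transforms", {
  set.seed(41)
  for (i in 1:10) {
    g <- list(rnorm(7), rnorm(5, 0.5), rnorm(6, -0.3))
    h1 <- kruskal_wallis(g)$H
    h2 <- kruskal_wallis(lapply(g, function(x) exp(3 * x)))$H
    h3 <- kruskal_wallis(lapply(g, function(x) atan(x) - 5))$H
    expect_equal(h2, h1)
    expect_equal(h3, h1)
  }
})

test_that("under the null, H averages near its degrees of freedom", {
  set.seed(42)
  h <- replicate(600, kruskal_wallis(list(rnorm(8), rnorm(8), rnorm(8)))$H)
  expect_lt(abs(mean(h) - 2), 0.15)  # E[chi2_2] = 2
})

test_that("chi-square p approximates the exact permutation p for tiny samples", {
  fixtures <- list(
    list(c(1.2, 3.4, 2.2), c(5.0, 4.1, 6.3), c(0.5, 2.9)),
    list(c(10, 12, 11), c(13, 15, 14), c(16, 18)),
    list(c(0.3, 0.9), c(0.1, 1.2, 0.4), c(0.8, 0.2, 1.0)))
  for (g in fixtures) {
    p_exact <- perm_kw_p(g)
    p_chisq <- kruskal_wallis(g)$p
    expect_lt(abs(p_chisq - p_exact), 0.1)
  }
})

test_that("LSD pairwise statistics match the hand-computed rank oracle", {
  g <- list(c(1, 2, 3), c(7, 8, 9), c(4, 5, 6))
  out <- lsd_pairwise(g)
  # pooled ranks are the values themselves; group means 2, 8, 5;
  # within-group SS = 2 + 2 + 2 on N - k = 6 df -> S2 = 1
  T12 <- abs(2 - 8) / sqrt(1 * (1 / 3 + 1 / 3))
  row12 <- out[out$group_i == "group1" & out$group_j == "group2", ]
  expect_equal(row12$T, T12)
  expect_equal(row12$df, 6)
  expect_equal(row12$p, 2 * pt(-T12, 6))
  expect_true(row12$significant)

  # identical interleaved groups: no separation
  same <- lsd_pairwise(list(c(1, 3, 5, 7), c(2, 4, 6, 8)))
  expect_lt(same$T, 1)
  expect_gt(same$p, 0.3)

  # p is strictly decreasing in |T| at fixed df
  expect_true(all(diff(2 * pt(-c(0.5, 1, 2, 4, 8), 6)) < 0))
  ord <- out[order(out$T), ]
  expect_true(all(diff(ord$p) <= 0))

  expect_error(lsd_pairwise(list(1, c(2, 3))), "at least 2 values")
})

test_that("condition comparison recovers a known sign pattern and protects LSD", {
  set.seed(70)
  eff <- data.frame(
    kind = c(rep("baseline", 40), rep("nod", 25), rep("nod", 25)),
    condition = c(rep("no_nodding_video", 40),
                  rep("with_video_not_forced", 25),
                  rep("with_video_forced", 25)),
    n = c(rnorm(40, 0, 2e-4), rnorm(25, -1e-3, 2e-4), rnorm(25, 1e-3, 2e-4)))
  cmp <- compare_conditions(eff, alpha = 0.05)
  expect_s3_class(cmp, "group_comparison")
  m <- cmp$mean_i
  expect_true(m[["not_forced_effect"]] < m[["baseline_no_nod_trend"]])
  expect_true(m[["baseline_no_nod_trend"]] < m[["forced_effect"]])
  expect_true(cmp$omnibus_significant)
  expect_identical(nrow(cmp$pairwise), 3L)
  expect_true(all(cmp$pairwise$significant))

  # spontaneous nods from no-video sessions belong to the not-forced group
  eff2 <- eff
  eff2$condition[41:45] <- "no_nodding_video"
  cmp2 <- compare_conditions(eff2)
  expect_equal(unname(cmp2$n_i), c(40L, 25L, 25L))

  # protection: a null data set withholds the pairwise table
  set.seed(77)
  null_eff <- data.frame(
    kind = c(rep("baseline", 15), rep("nod", 30)),
    condition = c(rep("no_nodding_video", 15),
                  rep("with_video_not_forced", 15),
                  rep("with_video_forced", 15)),
    n = rnorm(45))
  cmp3 <- compare_conditions(null_eff, alpha = 0.05)
  if (!cmp3$omnibus_significant) expect_null(cmp3$pairwise)
  cmp4 <- compare_conditions(null_eff, protect = FALSE)
  expect_identical(nrow(cmp4$pairwise), 3L)

  expect_error(compare_conditions(eff[eff$kind == "nod", ]), "baseline")
})

test_that("rejection power is non-decreasing in per-group sample size", {
  set.seed(88)
  power_at <- function(n) {
    mean(replicate(150, {
      g <- list(rnorm(n, 0), rnorm(n, 0.6), rnorm(n, -0.6))
      kruskal_wallis(g)$p < 0.05
    }))
  }
  p10 <- power_at(10); p30 <- power_at(30); p100 <- power_at(100)
  expect_true(p10 <= p30 + 0.05 && p30 <= p100 + 0.05)
  expect_gt(p100, 0.95)
})
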