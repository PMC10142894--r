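#' Kruskal-Wallis test with tie correction
#'
#' Rank-based k-sample test of identical distributions. Mid-ranks are
#' assigned over the pooled sample; the statistic is
#' `H = [12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)] / C` with the tie
#' correction `C = 1 - sum(t_j^3 - t_j) / (N^3 - N)` over tie groups of size
#' `t_j`. Under the null `H` is approximately chi-square with `k - 1`
#' degrees of freedom.
#'
#' @param groups list of numeric vectors, one per group (`k >= 2`, each
#'   non-empty, pooled size `>= 3`, not all values identical).
#' @return A list with `H`, `df`, `p`, per-group sizes `n_i` and mean ranks
#'   `rbar_i`.
#' @export
#' @examples
#' kruskal_wallis(list(1:3, 4:6, 7:9))$H  # 7.2
kruskal_wallis <- function(groups) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 1L)) stop("every group needs at least one value", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  if (N < 3L) stop("pooled sample must have at least 3 values", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("degenerate data: all pooled values identical", call. = FALSE)
  }
  r <- rank(x)  # mid-ranks
  g <- rep(seq_len(k), n_i)
  R_i <- tapply(r, g, sum)
  H0 <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H0 / C
  df <- k - 1L
  list(H = H, df = df, p = stats::pchisq(H, df, lower.tail = FALSE),
       n_i = as.numeric(n_i), rbar_i = as.numeric(R_i / n_i))
}

#' Pairwise least-significant-difference comparisons
#'
#' Fisher's LSD applied after an omnibus rank test: for each pair of groups
#' the statistic `T = |m_i - m_j| / sqrt(S2 (1/n_i + 1/n_j))` where, on the
#' default rank scale (Conover's procedure), `m_i` are mean pooled mid-ranks
#' and `S2` is the pooled within-group variance of the ranks on `N - k`
#' degrees of freedom; a raw-scale option uses the observations directly.
#' Two-sided p-values come from the t distribution with `N - k` df. No
#' multiplicity adjustment is applied beyond the protection step — that is
#' the LSD method; run it only after a significant omnibus test.
#'
#' @param groups list of numeric vectors, one per group.
#' @param alpha significance level for flagging pairs.
#' @param on_ranks compare pooled mid-ranks (default) rather than raw values.
#' @param labels optional group names.
#' @return Data frame with one row per pair: `group_i`, `group_j`, `T`,
#'   `df`, `p`, `significant`.
#' @export
lsd_pairwise <- function(groups, alpha = 0.05, on_ranks = TRUE,
                         labels = NULL) {
  k <- length(groups)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  n_i <- lengths(groups)
  if (any(n_i < 2L)) {
    stop("insufficient data: every group needs at least 2 values for LSD",
         call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  v <- if (on_ranks) rank(x) else x
  g <- rep(seq_len(k), n_i)
  m <- tapply(v, g, mean)
  ss_within <- sum(tapply(v, g, function(z) sum((z - mean(z))^2)))
  df <- N - k
  S2 <- ss_within / df
  pairs <- utils::combn(k, 2L)
  T_stat <- p <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt(S2 * (1 / n_i[i] + 1 / n_i[j]))
    T_stat[c] <- if (se > 0) abs(m[i] - m[j]) / se else 0
    p[c] <- 2 * stats::pt(-T_stat[c], df)
  }
  data.frame(group_i = labels[pairs[1L, ]], group_j = labels[pairs[2L, ]],
             T = T_stat, df = df, p = p, significant = p < alpha)
}

#' Three-condition comparison of effect distributions
#'
#' Assembles the three samples of the study design from pooled effect
#' values — the nod-free baseline trend values (all sessions), the per-nod
#' effects from the non-forced conditions (spontaneous nodding, whether or
#' not a nodding video was shown, both lecture halves), and the per-nod
#' effects from the forced condition — then runs the tie-corrected
#' Kruskal-Wallis test and, if it is significant at `omnibus_alpha`
#' (protected LSD; `protect = FALSE` overrides), the pairwise LSD
#' comparisons.
#'
#' @param effects an `effect_samples` data frame (rows from several sessions
#'   concatenated, e.g. with `rbind`), or any data frame with columns
#'   `kind`, `condition`, `n`.
#' @param alpha pairwise significance level.
#' @param omnibus_alpha level for the protection step (the study protocol
#'   screened at 0.1; default 0.05).
#' @param on_ranks perform LSD on pooled mid-ranks (default) or raw values.
#' @param protect require omnibus significance before flagging pairs.
#' @return A list of class `group_comparison`: group labels, sizes, means,
#'   `kruskal` (H, df, p), `pairwise` (LSD table or `NULL` when protection
#'   fails), and per-session counts.
#' @export
compare_conditions <- function(effects, alpha = 0.05,
                               omnibus_alpha = alpha, on_ranks = TRUE,
                               protect = TRUE) {
  stopifnot(all(c("kind", "condition", "n") %in% names(effects)))
  grp <- list(
    baseline_no_nod_trend = effects$n[effects$kind == "baseline"],
    not_forced_effect = effects$n[effects$kind == "nod" &
                                    effects$condition != "with_video_forced"],
    forced_effect = effects$n[effects$kind == "nod" &
                                effects$condition == "with_video_forced"])
  for (nm in names(grp)) {
    if (!length(grp[[nm]])) {
      stop(sprintf("empty group: %s", nm), call. = FALSE)
    }
  }
  kw <- kruskal_wallis(grp)
  significant <- kw$p < omnibus_alpha
  pairwise <- if (significant || !protect) {
    lsd_pairwise(grp, alpha = alpha, on_ranks = on_ranks,
                 labels = names(grp))
  } else NULL
  per_session <- if ("session_id" %in% names(effects)) {
    as.data.frame(table(session_id = effects$session_id,
                        kind = effects$kind))
  } else NULL
  structure(
    list(groups = names(grp),
         n_i = lengths(grp),
         mean_i = vapply(grp, mean, numeric(1L)),
         kruskal = kw[c("H", "df", "p")],
         omnibus_alpha = omnibus_alpha,
         omnibus_significant = significant,
         pairwise = pairwise,
         per_session_counts = per_session),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Three-condition comparison of effect values\n")
  tab <- data.frame(group = x$groups, n = as.integer(x$n_i),
                    mean_per_s = sprintf("%.3e", x$mean_i),
                    reading = ifelse(x$mean_i < 0, "arousal-increasing",
                                     "arousal-decreasing"))
  print(tab, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.3g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  if (is.null(x$pairwise)) {
    cat(sprintf("Omnibus not significant at alpha = %g; LSD withheld.\n",
                x$omnibus_alpha))
  } else {
    cat("Protected LSD pairwise comparisons (pooled mid-ranks):\n")
    pw <- x$pairwise
    pw$T <- sprintf("%.3f", pw$T)
    pw$p <- sprintf("%.3g", pw$p)
    print(pw, row.names = FALSE)
  }
  invisible(x)
}
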