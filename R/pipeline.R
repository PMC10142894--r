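#' Analyse one recording end to end
#'
#' Convenience wrapper running the per-session stages in order: artefact
#' rejection, sliding pNN50, per-nod effects and the matched non-nod
#' baseline.
#'
#' @param rri an [rri_series()].
#' @param events the matching [event_track()].
#' @param cfg an [effect_config()].
#' @param window_beats pNN50 window length in beats.
#' @param artifact_rejection apply [reject_artifacts()] first (default TRUE).
#' @return List with elements `pnn50` (`metric_series`), `effects` (nod and
#'   baseline `effect_samples` row-bound), `n_all`, `exclusions`,
#'   `rejections`.
#' @export
analyze_session <- function(rri, events, cfg = effect_config(),
                            window_beats = 100L,
                            artifact_rejection = TRUE) {
  if (artifact_rejection) rri <- reject_artifacts(rri)
  pnn <- compute_pnn50(rri, window_beats = window_beats)
  nod <- nodding_effects(pnn, events, cfg)
  base <- baseline_effects(pnn, events, cfg)
  eff <- rbind(as.data.frame(nod), as.data.frame(base))
  class(eff) <- c("effect_samples", "data.frame")
  attr(eff, "t0_s") <- cfg$t0_s
  list(pnn50 = pnn,
       effects = eff,
       n_all = if (nrow(eff)) eff$n_all[1L] else NA_real_,
       exclusions = rbind(tag_exclusions(nod, "nod"),
                          tag_exclusions(base, "baseline")),
       rejections = attr(rri, "rejections"))
}

#' Run a full study analysis
#'
#' Orchestrates the whole pipeline over a study configuration: for each
#' listed recording, load the RRI series and annotations, reject artefacts,
#' compute pNN50, derive per-nod and baseline effect values (each recording
#' is one continuous segment with its own session trend), then pool all
#' effect values and compare the three conditions. Identical reruns on the
#' same inputs produce identical results apart from the timestamps recorded
#' in the report.
#'
#' @param config a `study_config` from [read_study_config()], or an
#'   equivalent list whose `sessions` entries are lists with elements
#'   `rri`/`events` (paths, or in-memory [rri_series()]/[event_track()]
#'   objects) plus `condition` and `half`.
#' @return A list of class `run_report`: configuration echo, per-session
#'   summaries, the pooled `effect_samples`, the [compare_conditions()]
#'   result, package version and timestamps. If `config$out_dir` is set, the
#'   pooled effects CSV and the report JSON are written there.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$sessions) || !length(config$sessions)) {
    stop("configuration lists no sessions", call. = FALSE)
  }
  started <- Sys.time()
  cfg <- effect_config(
    t0_s = config$t0_s %||% 60,
    baseline_guard_s = config$baseline_guard_s %||% (config$t0_s %||% 60),
    sleep_policy = config$sleep_policy %||% "include",
    baseline_stride_s = config$baseline_stride_s)
  wb <- config$window_beats %||% 100L

  summaries <- vector("list", length(config$sessions))
  all_eff <- vector("list", length(config$sessions))
  for (i in seq_along(config$sessions)) {
    s <- config$sessions[[i]]
    rri <- if (inherits(s$rri, "rri_series")) s$rri else {
      read_rri_csv(s$rri, session_id = s$id %||% NULL)
    }
    events <- if (inherits(s$events, "event_track")) s$events else {
      read_events_csv(s$events, condition = s$condition,
                      half = s$half %||% "second",
                      session_id = session_id(rri))
    }
    res <- tryCatch(
      analyze_session(rri, events, cfg, window_beats = wb),
      error = function(e) {
        stop(sprintf("session %s (stage: per-session analysis): %s",
                     session_id(rri), conditionMessage(e)), call. = FALSE)
      })
    all_eff[[i]] <- as.data.frame(res$effects)
    summaries[[i]] <- data.frame(
      session_id = session_id(rri),
      condition = events$condition,
      half = events$half,
      n_beats = nrow(rri),
      n_rejected_beats = nrow(res$rejections),
      n_nods = length(events$nods),
      n_nod_effects = sum(res$effects$kind == "nod"),
      n_nod_excluded = sum(res$exclusions$kind == "nod"),
      n_baseline = sum(res$effects$kind == "baseline"),
      n_all_per_s = res$n_all)
  }
  effects <- do.call(rbind, all_eff)
  class(effects) <- c("effect_samples", "data.frame")
  attr(effects, "t0_s") <- cfg$t0_s
  comparison <- compare_conditions(
    effects, alpha = config$alpha %||% 0.05,
    omnibus_alpha = config$omnibus_alpha %||% (config$alpha %||% 0.05))

  report <- structure(
    list(config = config[setdiff(names(config), "sessions")],
         sessions = do.call(rbind, summaries),
         effects = effects,
         comparison = comparison,
         version = as.character(utils::packageVersion("nodeffect")),
         seed = config$seed %||% NA,
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(effects),
                     file.path(config$out_dir, "effects.csv"),
                     row.names = FALSE)
    writeLines(format_report_json(report),
               file.path(config$out_dir, "report.json"))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tag_exclusions <- function(eff, kind) {
  ex <- attr(eff, "exclusions")
  data.frame(kind = rep(kind, nrow(ex)), anchor_t = ex$anchor_t,
             reason = ex$reason)
}

#' Serialise a run report as canonical JSON
#'
#' Deterministic serialisation of the analysis content of a [run_pipeline()]
#' report: timestamps are omitted so that identical inputs yield
#' byte-identical JSON, which supports snapshot ("golden file") regression
#' testing of whole runs.
#'
#' @param report a `run_report`.
#' @return A JSON string.
#' @export
format_report_json <- function(report) {
  cmp <- report$comparison
  x <- list(
    version = report$version,
    config = report$config,
    sessions = report$sessions,
    groups = data.frame(group = cmp$groups, n = as.integer(cmp$n_i),
                        mean_per_s = as.numeric(cmp$mean_i)),
    kruskal = cmp$kruskal,
    omnibus_alpha = cmp$omnibus_alpha,
    omnibus_significant = cmp$omnibus_significant,
    pairwise = cmp$pairwise)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(15),
                                pretty = TRUE, null = "null"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d sessions, %d effect values (nodeffect %s)\n",
              nrow(x$sessions), nrow(x$effects), x$version))
  print(x$comparison)
  invisible(x)
}

#' Plot a session's pNN50 trace with nod markers
#'
#' Shows the sliding pNN50 series, the session trend line (dashed), nod
#' onsets as points on the trace and sleep spans as shaded rectangles —
#' the standard per-participant view of the event-locked analysis.
#'
#' @param metric a valid pNN50 `metric_series`.
#' @param events the matching [event_track()].
#' @param file optional output path (written with [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly if written to file.
#' @export
plot_session <- function(metric, events, file = NULL) {
  stopifnot(inherits(metric, "metric_series"))
  ok <- metric$valid & !is.na(metric$value)
  if (!any(ok)) stop("no valid metric samples to plot", call. = FALSE)
  df <- data.frame(t = metric$t[ok], value = metric$value[ok])
  slope <- global_trend(metric)
  intercept <- mean(df$value) - slope * mean(df$t)
  nods <- data.frame(t = events$nods,
                     value = metric_at(metric, events$nods))
  nods <- nods[!is.na(nods$value), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_abline(slope = slope, intercept = intercept,
                         linetype = "dashed", colour = "blue") +
    ggplot2::labs(x = "time (s)", y = "pNN50",
                  title = sprintf("Session %s (%s)", events$session_id,
                                  events$condition)) +
    ggplot2::theme_minimal()
  if (nrow(events$sleep)) {
    p <- p + ggplot2::geom_rect(
      data = data.frame(xmin = events$sleep$start, xmax = events$sleep$end),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.4)
  }
  if (nrow(nods)) {
    p <- p + ggplot2::geom_point(data = nods, colour = "red", size = 1.5)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 4, dpi = 150)
    return(invisible(p))
  }
  p
}
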