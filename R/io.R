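#' Read an RR-interval recording from CSV
#'
#' Expects a header with columns `time_s,rri_ms`; `time_s` may be absent, in
#' which case beat times are reconstructed as the cumulative sum of the
#' intervals. Rows with non-positive intervals or non-monotone times raise a
#' validation error that enumerates the offending rows; nothing is dropped
#' silently.
#'
#' @param path path to a CSV file.
#' @param session_id identifier for the recording; defaults to the file name
#'   without extension.
#' @return An [rri_series()].
#' @export
read_rri_csv <- function(path, session_id = NULL) {
  if (is.null(session_id)) session_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"rri_ms" %in% names(df)) {
    stop(sprintf("'%s': missing required column 'rri_ms'", path), call. = FALSE)
  }
  t <- if ("time_s" %in% names(df)) as.numeric(df$time_s) else NULL
  rri_series(as.numeric(df$rri_ms), t = t, session_id = session_id)
}

#' Write an RR-interval recording to CSV
#'
#' Writes columns `time_s,rri_ms`. Intervals are stored in milliseconds
#' (lossless for sensors deriving RRI from a 1 kHz ECG); round-tripping with
#' [read_rri_csv()] reproduces the series exactly at the written precision.
#'
#' @param series an [rri_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rri_csv <- function(series, path) {
  stopifnot(inherits(series, "rri_series"))
  df <- data.frame(time_s = fmt_num(series$t), rri_ms = fmt_num(series$rri))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Shortest decimal representation that survives read-back exactly.
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Read a nod/sleep annotation track from CSV
#'
#' The dialect is `kind,start_s,end_s` with `kind` either `nod` (point
#' event; `end_s` empty) or `sleep` (interval). Out-of-order nods are sorted
#' and duplicates removed, each with a warning.
#'
#' @param path path to a CSV file.
#' @param condition,half,session_id metadata for the track; `session_id`
#'   defaults to the file name.
#' @return An [event_track()].
#' @export
read_events_csv <- function(path,
                            condition = "no_nodding_video",
                            half = "second", session_id = NULL) {
  if (is.null(session_id)) session_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(kind = "character"))
  need <- c("kind", "start_s", "end_s")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s': expected columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  }
  bad <- setdiff(unique(df$kind), c("nod", "sleep"))
  if (length(bad)) {
    stop(sprintf("'%s': unknown event kind(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  nods <- as.numeric(df$start_s[df$kind == "nod"])
  sl <- df[df$kind == "sleep", , drop = FALSE]
  sleep <- if (nrow(sl)) {
    data.frame(start = as.numeric(sl$start_s), end = as.numeric(sl$end_s))
  } else NULL
  event_track(nods = nods, sleep = sleep, condition = condition,
              half = half, session_id = session_id)
}

#' Write a nod/sleep annotation track to CSV
#'
#' @param track an [event_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(track, path) {
  stopifnot(inherits(track, "event_track"))
  df <- rbind(
    data.frame(kind = rep("nod", length(track$nods)),
               start_s = fmt_num(track$nods),
               end_s = rep("", length(track$nods))),
    data.frame(kind = rep("sleep", nrow(track$sleep)),
               start_s = fmt_num(track$sleep$start),
               end_s = fmt_num(track$sleep$end)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read annotations from an ELAN tab-delimited export
#'
#' Parses the "Export as tab-delimited text" format produced by the ELAN
#' annotation tool: one row per annotation with tier name, begin time, end
#' time (ss.msec) and annotation value. Every annotation interval on the nod
#' tier becomes exactly one nod event anchored at its begin time — a bout of
#' several head bobs annotated as a single interval therefore counts as one
#' nod. Intervals on the sleep tier become sleep spans.
#'
#' @param path path to the exported text file.
#' @param nod_tier,sleep_tier tier names to read; `sleep_tier = NULL` skips
#'   sleep parsing.
#' @param condition,half,session_id metadata for the resulting track.
#' @return An [event_track()].
#' @export
read_events_elan_export <- function(path, nod_tier = "nod",
                                    sleep_tier = "sleep",
                                    condition = "no_nodding_video",
                                    half = "second", session_id = NULL) {
  if (is.null(session_id)) session_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(event_track(condition = condition, half = half,
                       session_id = session_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tiers <- vapply(parts, `[[`, "", 1L)
  known <- c(nod_tier, sleep_tier)
  if (!any(tiers %in% known)) {
    stop(sprintf("'%s': no rows on tier(s) %s; tiers present: %s", path,
                 paste(known, collapse = "/"),
                 paste(unique(tiers), collapse = ", ")), call. = FALSE)
  }
  parse_time <- function(s, line_no) {
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v)) {
      stop(sprintf("'%s' line %d: unparseable time '%s'", path, line_no, s),
           call. = FALSE)
    }
    v
  }
  nods <- numeric(); ss <- numeric(); se <- numeric()
  for (i in seq_along(parts)) {
    row <- parts[[i]]
    if (length(row) < 3L) next
    if (row[1L] == nod_tier) {
      nods <- c(nods, parse_time(row[2L], i))
    } else if (!is.null(sleep_tier) && row[1L] == sleep_tier) {
      ss <- c(ss, parse_time(row[2L], i))
      se <- c(se, parse_time(row[3L], i))
    }
  }
  sleep <- if (length(ss)) data.frame(start = ss, end = se) else NULL
  event_track(nods = nods, sleep = sleep, condition = condition,
              half = half, session_id = session_id)
}

#' Read a study configuration from YAML
#'
#' The configuration lists the recordings of a study (RRI file, events file,
#' condition, half) and the analysis parameters (pNN50 window, lag `t0`,
#' significance level, output directory). See the package vignette for the
#' schema. All referenced files must exist.
#'
#' @param path path to a YAML file.
#' @return A list of class `study_config`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  if (is.null(cfg$sessions) || !length(cfg$sessions)) {
    stop("study config lists no sessions", call. = FALSE)
  }
  for (i in seq_along(cfg$sessions)) {
    s <- cfg$sessions[[i]]
    for (f in c("rri", "events")) {
      if (is.null(s[[f]])) {
        stop(sprintf("session %d: missing '%s' path", i, f), call. = FALSE)
      }
      p <- s[[f]]
      if (!file.exists(p)) p <- file.path(base, s[[f]])
      if (!file.exists(p)) {
        stop(sprintf("session %d: file not found: %s", i, s[[f]]),
             call. = FALSE)
      }
      cfg$sessions[[i]][[f]] <- p
    }
    cond <- s$condition
    if (is.null(cond) || !cond %in% c("no_nodding_video",
                                      "with_video_not_forced",
                                      "with_video_forced")) {
      stop(sprintf("session %d: invalid condition '%s'", i,
                   if (is.null(cond)) "<missing>" else cond), call. = FALSE)
    }
  }
  defaults <- list(window_beats = 100L, t0_s = 60, baseline_guard_s = 60,
                   baseline_stride_s = NULL, sleep_policy = "include",
                   alpha = 0.05, omnibus_alpha = 0.05, out_dir = NULL)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  structure(cfg, class = "study_config")
}
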