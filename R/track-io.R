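#' Construct a session-tracks object
#'
#' Bundles per-subject time-stamped positions with their condition and
#' session labels. Most users obtain one from [read_tracks()],
#' [fixture_from_zone_timeline()], or [simulate_session()] rather than
#' calling this directly.
#'
#' @param data Long-format data frame with columns `time_s`, `subject_id`,
#'   `x_cm`, `y_cm`, one row per sample per subject.
#' @param condition A [condition_spec()].
#' @param dt_s Common sampling interval if the tracks are already on a
#'   shared regular grid, else `NA` (call [resample_tracks()] before
#'   scoring).
#' @param session_id,day_index,pair_id Session labels.
#' @return An object of class `session_tracks`.
#' @export
session_tracks <- function(data, condition = condition_spec(), dt_s = NA_real_,
                           session_id = "s1", day_index = 1L,
                           pair_id = "pair1") {
  required <- c("time_s", "subject_id", "x_cm", "y_cm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop_validation("track data is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  data$subject_id <- as.character(data$subject_id)
  if (nrow(data) == 0L) stop_validation("track data has no samples")
  if (any(!is.finite(data$time_s)) || any(data$time_s < 0))
    stop_validation("timestamps must be finite and >= 0 (offending row(s): ",
                    paste(utils::head(which(!is.finite(data$time_s) |
                                              data$time_s < 0), 5L),
                          collapse = ", "), ")")
  if (any(!is.finite(data$x_cm)) || any(!is.finite(data$y_cm)))
    stop_validation("positions must be finite (offending row(s): ",
                    paste(utils::head(which(!is.finite(data$x_cm) |
                                              !is.finite(data$y_cm)), 5L),
                          collapse = ", "), ")")
  subjects <- unique(data$subject_id)
  if (length(subjects) > 2L)
    stop_validation("at most 2 subjects supported, found ",
                    length(subjects), ": ", paste(subjects, collapse = ", "))
  expected <- n_subjects_for_mode(condition$mode)
  if (length(subjects) != expected)
    stop_validation(condition$mode, " mode requires exactly ", expected,
                    " subject(s), found ", length(subjects))
  data <- data[order(data$subject_id, data$time_s), , drop = FALSE]
  rownames(data) <- NULL
  for (s in subjects) {
    ts <- data$time_s[data$subject_id == s]
    if (any(diff(ts) <= 0)) {
      k <- which(diff(ts) <= 0)[1L]
      stop_validation("timestamps for subject '", s,
                      "' are not strictly increasing near t = ", ts[k])
    }
  }
  structure(list(data = data, subjects = subjects, dt_s = as.numeric(dt_s),
                 condition = condition, session_id = session_id,
                 day_index = as.integer(day_index), pair_id = pair_id),
            class = "session_tracks")
}

#' @export
print.session_tracks <- function(x, ...) {
  cat(sprintf("Session tracks '%s' (pair %s, day %d): %d subject(s)\n",
              x$session_id, x$pair_id, x$day_index, length(x$subjects)))
  for (s in x$subjects) {
    d <- x$data[x$data$subject_id == s, ]
    cat(sprintf("  %s: %d samples, t in [%.2f, %.2f] s\n",
                s, nrow(d), min(d$time_s), max(d$time_s)))
  }
  cat(if (is.na(x$dt_s)) "  not on a shared grid (resample before scoring)\n"
      else sprintf("  shared grid at dt = %g s\n", x$dt_s))
  print(x$condition)
  invisible(x)
}

subject_track <- function(tracks, s) {
  tracks$data[tracks$data$subject_id == s, , drop = FALSE]
}

#' Read subject tracks from a delimited text file
#'
#' Expects the long-format tracker export convention: a comma-delimited
#' UTF-8 file with header `time_s,subject_id,x_cm,y_cm`, one row per sample
#' per subject. Other headers can be accommodated through `col_map`.
#'
#' @param path Path to the track file.
#' @param condition A [condition_spec()]; the subject count in the file must
#'   match its `mode`.
#' @param col_map Named character vector mapping the canonical names
#'   `time_s`, `subject_id`, `x_cm`, `y_cm` to the file's column names.
#' @param ... Passed to [session_tracks()] (session labels).
#' @return A [session_tracks()] object (per-subject time-sorted, validated).
#' @export
read_tracks <- function(path, condition = condition_spec(),
                        col_map = c(time_s = "time_s",
                                    subject_id = "subject_id",
                                    x_cm = "x_cm", y_cm = "y_cm"), ...) {
  if (!file.exists(path))
    stop_validation("track file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(col_map), names(raw))
  if (length(missing_cols))
    stop_validation("track file ", path, " is missing column(s): ",
                    paste(missing_cols, collapse = ", "),
                    " (header line 1)")
  df <- data.frame(time_s = as.numeric(raw[[col_map[["time_s"]]]]),
                   subject_id = as.character(raw[[col_map[["subject_id"]]]]),
                   x_cm = as.numeric(raw[[col_map[["x_cm"]]]]),
                   y_cm = as.numeric(raw[[col_map[["y_cm"]]]]))
  withCallingHandlers(
    session_tracks(df, condition = condition, ...),
    coopmaze_validation_error = function(e) {
      # row k of the data frame is line k + 1 of the file (header)
      e$message <- paste0(path, ": ", conditionMessage(e),
                          " [data rows; add 1 for the header line]")
      stop(e)
    })
}

#' Write tracks to the canonical CSV dialect
#'
#' @param tracks A [session_tracks()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  utils::write.csv(tracks$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample tracks onto a shared regular grid
#'
#' Linearly interpolates each subject's x and y onto a common grid with
#' spacing `dt_s`, running from 0 (or the latest first timestamp, if a track
#' starts later) to the earliest per-subject last timestamp. No
#' extrapolation is performed. Gaps between consecutive input samples longer
#' than `gap_warn_s` are reported as warnings but still interpolated: the
#' scoring engine has no missing-data concept.
#'
#' @param tracks A [session_tracks()] object.
#' @param dt_s Target sampling interval (s). Default 0.04 (25 Hz, a common
#'   video frame rate).
#' @param gap_warn_s Gap length that triggers a warning. Default 1 s.
#' @return A [session_tracks()] object on the shared grid, with `dt_s` set.
#' @export
resample_tracks <- function(tracks, dt_s = 0.04, gap_warn_s = 1) {
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0)
    stop_validation("dt_s must be a single positive number")
  per <- lapply(tracks$subjects, function(s) subject_track(tracks, s))
  if (any(vapply(per, nrow, 1L) < 2L))
    stop_validation("each subject needs at least 2 samples to resample")
  t_lo <- max(vapply(per, function(d) d$time_s[1L], 1))
  t_hi <- min(vapply(per, function(d) d$time_s[nrow(d)], 1))
  grid <- seq(0, t_hi, by = dt_s)
  grid <- grid[grid >= t_lo - 1e-12]
  if (length(grid) == 0L)
    stop_validation("requested grid is empty (tracks overlap on [",
                    signif(t_lo, 6), ", ", signif(t_hi, 6), "] s)")
  out <- do.call(rbind, lapply(seq_along(tracks$subjects), function(i) {
    d <- per[[i]]
    gaps <- diff(d$time_s)
    if (any(gaps > gap_warn_s))
      warning(sprintf(
        "subject '%s': %d inter-sample gap(s) longer than %g s interpolated",
        tracks$subjects[i], sum(gaps > gap_warn_s), gap_warn_s),
        call. = FALSE)
    data.frame(time_s = grid,
               subject_id = tracks$subjects[i],
               x_cm = stats::approx(d$time_s, d$x_cm, xout = grid,
                                    ties = "ordered")$y,
               y_cm = stats::approx(d$time_s, d$y_cm, xout = grid,
                                    ties = "ordered")$y)
  }))
  res <- session_tracks(out, condition = tracks$condition, dt_s = dt_s,
                        session_id = tracks$session_id,
                        day_index = tracks$day_index,
                        pair_id = tracks$pair_id)
  res
}

EVENT_KINDS <- c("trial_armed", "reward", "break", "session_end")

empty_event_log <- function() {
  data.frame(t_s = numeric(0), event = character(0),
             zone_1 = character(0), zone_2 = character(0),
             detail = character(0),
             reward_volume_ul = numeric(0), pump_duration_s = numeric(0),
             stringsAsFactors = FALSE)
}

validate_event_log <- function(log) {
  required <- names(empty_event_log())
  missing_cols <- setdiff(required, names(log))
  if (length(missing_cols))
    stop_validation("event log is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  if (nrow(log)) {
    if (is.unsorted(log$t_s))
      stop_validation("event log must be time-ordered")
    if (!all(log$event %in% EVENT_KINDS))
      stop_validation("unknown event kind(s): ",
                      paste(setdiff(unique(log$event), EVENT_KINDS),
                            collapse = ", "))
    ends <- which(log$event == "session_end")
    if (length(ends) > 1L || (length(ends) == 1L && ends != nrow(log)))
      stop_validation("at most one session_end event, and it must be last")
  }
  log[required]
}

#' Write an event log to disk
#'
#' @param log Event-log data frame (as found in a
#'   [run_session()] result's `events`).
#' @param path Output path.
#' @param format `"csv"` (fixed column order, default) or `"jsonl"`
#'   (JSON-lines, one event object per line, for programmatic use).
#' @return `path`, invisibly.
#' @seealso [read_events()]
#' @export
write_events <- function(log, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  log <- validate_event_log(log)
  if (format == "csv") {
    utils::write.csv(log, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    if (nrow(log))
      for (k in seq_len(nrow(log)))
        writeLines(jsonlite::toJSON(as.list(log[k, ]), auto_unbox = TRUE,
                                    digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read an event log written by [write_events()]
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`.
#' @return Event-log data frame.
#' @export
read_events <- function(path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("event file not found: ", path)
  if (format == "csv") {
    log <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(t_s = "numeric", event = "character",
                                          zone_1 = "character",
                                          zone_2 = "character",
                                          detail = "character",
                                          reward_volume_ul = "numeric",
                                          pump_duration_s = "numeric"))
    log$detail[is.na(log$detail)] <- ""
  } else {
    lines <- readLines(path)
    log <- if (length(lines) == 0L) empty_event_log() else
      do.call(rbind, lapply(lines, function(l) {
        rec <- jsonlite::fromJSON(l)
        rec[vapply(rec, is.null, TRUE)] <- NA
        as.data.frame(rec, stringsAsFactors = FALSE)
      }))
    if (nrow(log)) log$detail[is.na(log$detail)] <- ""
  }
  validate_event_log(log)
}

#' Build deterministic tracks from a per-subject zone timeline
#'
#' The workhorse fixture generator for engine tests: given, for each
#' subject, a sequence of `(zone, dwell seconds)` pairs, produces tracks
#' whose [zone_of()] sequence equals the requested timeline exactly.
#' Positions sit at zone centres; crossings between dwells are instantaneous
#' (the position jumps between consecutive samples). Dwells are half-open:
#' a dwell of `d` seconds occupies samples `t, t + dt, ..., t + d - dt`.
#'
#' If the subjects' timelines have different total durations, both tracks
#' are truncated to the shorter one (the shared-grid rule).
#'
#' @param timeline For one subject, a list of `list(zone, dwell_s)` (or
#'   2-element vectors); for two, a list of two such lists.
#' @param geom A [maze_geometry()].
#' @param dt_s Sampling interval; every dwell must be a positive multiple.
#' @param condition A [condition_spec()]; its mode must match the number of
#'   timelines.
#' @param ... Session labels passed to [session_tracks()].
#' @return A [session_tracks()] object on a shared grid starting at t = 0.
#' @examples
#' tl <- list(list("A", 5), list("B", 5), list("C", 5))
#' trk <- fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1)
#' table(zone_of(trk$data$x_cm))
#' @export
fixture_from_zone_timeline <- function(timeline, geom = maze_geometry(),
                                       dt_s = 0.04,
                                       condition = NULL, ...) {
  single <- length(timeline) > 0L &&
    !is.list(timeline[[1L]][[1L]]) && length(timeline[[1L]]) == 2L &&
    (is.character(timeline[[1L]][[1L]]) || is.character(timeline[[1L]][1L]))
  timelines <- if (single) list(timeline) else timeline
  n_sub <- length(timelines)
  if (!n_sub %in% 1:2)
    stop_validation("timeline must describe 1 or 2 subjects")
  if (is.null(condition))
    condition <- condition_spec(mode = if (n_sub == 2L) "paired" else "solitary")
  centres <- zone_centres(geom)
  lane_y <- lane_centres(geom)
  seqs <- lapply(timelines, function(tl) {
    zz <- integer(0)
    for (seg in tl) {
      zone <- as.character(seg[[1L]])
      dwell <- as.numeric(seg[[2L]])
      code <- match(zone, ZONE_LABELS)
      if (is.na(code)) stop_validation("unknown zone label '", zone, "'")
      n_i <- round(dwell / dt_s)
      if (n_i < 1L || abs(n_i * dt_s - dwell) > 1e-8)
        stop_validation("dwell ", dwell,
                        " s is not a positive multiple of dt_s = ", dt_s)
      zz <- c(zz, rep.int(code, n_i))
    }
    zz
  })
  n <- min(lengths(seqs))
  if (n == 0L) stop_validation("empty timeline")
  df <- do.call(rbind, lapply(seq_len(n_sub), function(i) {
    z <- seqs[[i]][seq_len(n)]
    data.frame(time_s = (seq_len(n) - 1L) * dt_s,
               subject_id = paste0("rat", i),
               x_cm = centres[z],
               y_cm = lane_y[min(i, length(lane_y))])
  }))
  session_tracks(df, condition = condition, dt_s = dt_s, ...)
}

zone_centres <- function(geom) {
  b <- geom$zone_bounds_cm
  c((0 + b[1]) / 2, (b[1] + b[2]) / 2, (b[2] + geom$length_cm) / 2)
}

lane_centres <- function(geom) {
  w <- geom$width_cm / geom$n_lanes
  (seq_len(geom$n_lanes) - 0.5) * w
}
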