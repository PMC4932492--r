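#' Path length of a track
#'
#' Total distance moved: the sum of Euclidean step distances between
#' consecutive samples of a (resampled) track. This is the standard tracker
#' operationalisation of locomotor activity.
#'
#' @param track Data frame with columns `x_cm` and `y_cm` (time-ordered), or
#'   a numeric vector of longitudinal positions.
#' @return Distance in cm (0, with a warning, for fewer than 2 samples).
#' @export
path_length <- function(track) {
  if (is.numeric(track)) track <- data.frame(x_cm = track, y_cm = 0)
  n <- nrow(track)
  if (n < 2L) {
    warning("fewer than 2 samples; path length is 0", call. = FALSE)
    return(0)
  }
  sum(sqrt(diff(track$x_cm)^2 + diff(track$y_cm)^2))
}

#' Per-session behavioral metrics
#'
#' Computes the assay's session-level measures from a scored result and its
#' tracks: reward count, locomotor activity (total path length, summed over
#' the pair), the efficacy index (rewards per cm of activity, the assay's
#' utility measure of cooperation), and the latency of the session's initial
#' A-to-C transition. Tracks are truncated at the scored duration first:
#' the session is over once a cap fires, so movement beyond it is not
#' scored.
#'
#' Latency is the first time both subjects simultaneously occupy zone C
#' (the subject's own first C entry in solitary mode), whether or not that
#' instant earned a reward; set `latency = "first_reward"` to use the first
#' reward instant instead. Sessions that never reach C get a missing
#' latency (`NA`), not an imputed cap.
#'
#' @param result A [run_session()] result.
#' @param tracks The [session_tracks()] the result was produced from.
#' @param geom The [maze_geometry()] used for scoring.
#' @param latency `"first_c"` (default) or `"first_reward"`.
#' @return A one-row data frame (a metric row) with `pair_id`, `day_index`,
#'   `condition` (compact label) plus `divider`, `context_cues`, `sex`,
#'   `mode`, and `rewards`, `n_breaks`, `activity_cm`, `activity_1_cm`,
#'   `activity_2_cm`, `efficacy` (0 when activity is 0), `latency_s`,
#'   `scored_duration_s`.
#' @export
session_metrics <- function(result, tracks, geom = maze_geometry(),
                            latency = c("first_c", "first_reward")) {
  latency <- match.arg(latency)
  if (!inherits(result, "session_result"))
    stop_validation("result must come from run_session()")
  if (!identical(result$session_id, tracks$session_id))
    stop_validation("session ids differ between result ('", result$session_id,
                    "') and tracks ('", tracks$session_id, "')")
  keep <- tracks$data$time_s <= result$scored_duration_s + 1e-9
  data <- tracks$data[keep, , drop = FALSE]
  per <- lapply(tracks$subjects,
                function(s) data[data$subject_id == s, , drop = FALSE])
  act <- vapply(per, path_length, 1)
  activity <- sum(act)
  rewards <- result$n_rewards
  efficacy <- if (activity > 0) rewards / activity else 0
  lat <- NA_real_
  if (latency == "first_reward") {
    rt <- result$events$t_s[result$events$event == "reward"]
    if (length(rt)) lat <- rt[1L]
  } else {
    zc <- lapply(per, function(d) zone_codes(d$x_cm, geom))
    in_c <- Reduce(`&`, lapply(zc, function(z) z == 3L))
    k <- which(in_c)[1L]
    if (!is.na(k)) lat <- per[[1L]]$time_s[k]
  }
  cond <- tracks$condition
  data.frame(pair_id = tracks$pair_id, day_index = tracks$day_index,
             condition = condition_label(cond),
             divider = cond$divider, context_cues = cond$context_cues,
             sex = cond$sex, mode = cond$mode,
             rewards = rewards, n_breaks = result$n_breaks,
             activity_cm = activity,
             activity_1_cm = act[1L],
             activity_2_cm = if (length(act) > 1L) act[2L] else NA_real_,
             efficacy = efficacy, latency_s = lat,
             scored_duration_s = result$scored_duration_s,
             stringsAsFactors = FALSE)
}

LC_METRICS <- c("rewards", "activity_cm", "efficacy", "latency_s")

#' Aggregate metric rows into a learning-curve table
#'
#' Groups per-session metric rows by `(day_index, condition)` and reports
#' mean, SEM (sample SD / sqrt(n)), and n for each metric. Missing
#' (censored) latencies are excluded from the latency cells with n adjusted
#' accordingly; cells with n = 1 get SEM `NA`.
#'
#' @param rows Data frame of metric rows from [session_metrics()] /
#'   [simulate_experiment()].
#' @return A data frame of class `coop_learning_curve` with one row per
#'   `(day_index, condition)` and columns `<metric>_mean`, `<metric>_sem`,
#'   `<metric>_n` for each of `rewards`, `activity_cm`, `efficacy`,
#'   `latency_s`.
#' @export
aggregate_days <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- data.frame(day_index = integer(0), condition = character(0))
    class(out) <- c("coop_learning_curve", "data.frame")
    return(out)
  }
  key <- interaction(rows$day_index, rows$condition, drop = TRUE)
  groups <- split(rows, key)
  out <- do.call(rbind, lapply(groups, function(g) {
    cell <- data.frame(day_index = g$day_index[1L],
                       condition = g$condition[1L],
                       stringsAsFactors = FALSE)
    for (m in LC_METRICS) {
      v <- g[[m]]
      v <- v[!is.na(v)]
      n <- length(v)
      cell[[paste0(m, "_mean")]] <- if (n) mean(v) else NA_real_
      cell[[paste0(m, "_sem")]] <- if (n > 1L) stats::sd(v) / sqrt(n) else NA_real_
      cell[[paste0(m, "_n")]] <- n
    }
    cell
  }))
  out <- out[order(out$condition, out$day_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coop_learning_curve", "data.frame")
  out
}

#' Per-day percent change of a metric versus a baseline day
#'
#' The assay's reporting convention for latency improvement: the reduction
#' relative to the first day, `100 * (baseline - value) / baseline`, so a
#' drop from 100 s to 17.4 s is an 82.6% reduction. The SEM is propagated
#' from the per-day and baseline cells by first-order error propagation
#' (cells treated as independent); the baseline day itself is reported as
#' exactly 0 with SEM 0.
#'
#' @param table A [aggregate_days()] learning-curve table containing a
#'   single condition.
#' @param metric One of `"rewards"`, `"activity_cm"`, `"efficacy"`,
#'   `"latency_s"`.
#' @param baseline_day Day index of the baseline. Default 1.
#' @return Data frame with `day_index`, `pct_change`, `pct_change_sem`.
#' @export
percent_change <- function(table, metric = "latency_s", baseline_day = 1L) {
  if (!metric %in% LC_METRICS)
    stop_validation("metric must be one of: ", paste(LC_METRICS, collapse = ", "))
  if (length(unique(table$condition)) > 1L)
    stop_validation("table mixes conditions; subset to one before ",
                    "computing percent change")
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sem")
  b_row <- which(table$day_index == baseline_day)
  if (!length(b_row))
    stop_validation("baseline day ", baseline_day, " not present")
  m_b <- table[[mcol]][b_row[1L]]
  s_b <- table[[scol]][b_row[1L]]
  if (is.na(m_b) || m_b == 0)
    stop_validation("baseline mean is zero or missing; percent change undefined")
  if (is.na(s_b)) s_b <- 0
  m_d <- table[[mcol]]
  s_d <- table[[scol]]
  s_d[is.na(s_d)] <- 0
  pc <- 100 * (m_b - m_d) / m_b
  sem <- sqrt((100 / m_b)^2 * s_d^2 + (100 * m_d / m_b^2)^2 * s_b^2)
  pc[table$day_index == baseline_day] <- 0
  sem[table$day_index == baseline_day] <- 0
  data.frame(day_index = table$day_index, pct_change = pc,
             pct_change_sem = sem)
}

#' Plot a learning curve
#'
#' Mean +/- SEM of a metric per day, one line per condition.
#'
#' @param x A [aggregate_days()] table.
#' @param metric Metric to plot (default `"rewards"`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.coop_learning_curve <- function(x, metric = "rewards", ...) {
  mcol <- paste0(metric, "_mean")
  scol <- paste0(metric, "_sem")
  if (!mcol %in% names(x)) stop_validation("metric not in table: ", metric)
  conds <- unique(x$condition)
  sem <- ifelse(is.na(x[[scol]]), 0, x[[scol]])
  ylim <- range(c(x[[mcol]] - sem, x[[mcol]] + sem), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$day_index), ylim = ylim,
                 xlab = "day", ylab = metric, ...)
  for (i in seq_along(conds)) {
    g <- x[x$condition == conds[i], ]
    g <- g[order(g$day_index), ]
    s <- ifelse(is.na(g[[scol]]), 0, g[[scol]])
    graphics::lines(g$day_index, g[[mcol]], col = i, type = "b", pch = 16)
    graphics::arrows(g$day_index, g[[mcol]] - s, g$day_index, g[[mcol]] + s,
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  if (length(conds) > 1L)
    graphics::legend("topleft", legend = conds, col = seq_along(conds),
                     lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
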