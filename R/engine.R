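BREAK_CAUSES <- c("two_zones_apart", "mismatch_timeout", "session_end")
END_CAUSES <- c("time_cap", "trial_cap", "track_end")

#' Score a session through the cooperation trial engine
#'
#' Replays resampled tracks through the assay's state machine. A trial is
#' armed when both subjects occupy zone A simultaneously and becomes active
#' when either leaves A. While active, the pair breaks the trial by being
#' more than one zone apart (A and C) at any sample, or by occupying
#' different zones for strictly more than `max_mismatch_s` continuous
#' seconds (the timer resets whenever they share a zone). The trial is
#' rewarded when both subjects are simultaneously in zone C, each having
#' visited B since arming (the A-then-B-then-C progression; backtracking is
#' allowed and does not reset progression). After any outcome the
#' coordination rules are suspended until both subjects are back in A,
#' which re-arms the next trial. The session ends at the first sample at or
#' beyond `max_session_s`, or at the first sample after the
#' `max_rewarded_trials`-th reward, whichever comes first; caps are checked
#' before any other rule at each sample.
#'
#' In solitary mode the partner-dependent rules degenerate to the single
#' subject's own zone: success is its own A-B-C traversal ending in C, and
#' re-arming its own return to A.
#'
#' If the first sample is not (both subjects) in zone A, the engine waits in
#' a pre-armed state until both are first observed in A; no trial can
#' complete before a first arming.
#'
#' @param tracks A [session_tracks()] object on a shared regular grid (see
#'   [resample_tracks()]); subject count must match `params$mode`.
#' @param params An [engine_params()].
#' @param geom A [maze_geometry()].
#' @return An object of class `session_result`: a list with `events` (the
#'   event log: trial_armed / reward / break / session_end rows; reward rows
#'   carry the pump volume and duration), `trials` (one row per armed trial
#'   with `t_armed`, `t_outcome`, `outcome`, `cause`), `n_rewards`,
#'   `n_breaks` (coordination breaks: two-zones-apart + mismatch-timeout),
#'   `n_interrupted` (trials cut open by the session end),
#'   `scored_duration_s`, `end_cause`, and echoes of the inputs.
#' @examples
#' tl <- list(list("A", 4), list("B", 4), list("C", 4))
#' trk <- fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1)
#' run_session(trk, engine_params())
#' @export
run_session <- function(tracks, params = engine_params(),
                        geom = maze_geometry()) {
  if (!inherits(tracks, "session_tracks"))
    stop_validation("tracks must be a session_tracks object")
  if (is.na(tracks$dt_s))
    stop_validation("tracks are not on a shared grid; ",
                    "call resample_tracks() first")
  n_sub <- length(tracks$subjects)
  if (n_sub != n_subjects_for_mode(params$mode))
    stop_validation(params$mode, " mode requires ",
                    n_subjects_for_mode(params$mode), " subject(s), tracks have ",
                    n_sub)
  per <- lapply(tracks$subjects, function(s) subject_track(tracks, s))
  ts <- per[[1L]]$time_s
  for (d in per[-1L])
    if (nrow(d) != length(ts) || any(abs(d$time_s - ts) > 1e-9))
      stop_validation("subject grids differ; call resample_tracks() first")
  z <- lapply(per, function(d) zone_codes(d$x_cm, geom))
  solitary <- params$mode == "solitary"
  raw <- run_session_cpp(z[[1L]], if (solitary) z[[1L]] else z[[2L]],
                         t0 = ts[1L], dt = tracks$dt_s,
                         max_mismatch_s = params$max_mismatch_s,
                         max_rewarded_trials = params$max_rewarded_trials,
                         max_session_s = params$max_session_s,
                         solitary = solitary)
  detail <- character(length(raw$ev_kind))
  is_break <- raw$ev_kind == 3L
  is_end <- raw$ev_kind == 4L
  detail[is_break] <- BREAK_CAUSES[raw$ev_detail[is_break]]
  detail[is_end] <- END_CAUSES[raw$ev_detail[is_end]]
  events <- data.frame(
    t_s = raw$ev_t,
    event = EVENT_KINDS[raw$ev_kind],
    zone_1 = ZONE_LABELS[raw$ev_z1],
    zone_2 = if (solitary) NA_character_ else ZONE_LABELS[raw$ev_z2],
    detail = detail,
    reward_volume_ul = ifelse(raw$ev_kind == 2L, params$reward_volume_ul,
                              NA_real_),
    pump_duration_s = ifelse(raw$ev_kind == 2L, params$pump_duration_s,
                             NA_real_),
    stringsAsFactors = FALSE)
  trials <- data.frame(
    t_armed = raw$tr_armed,
    t_outcome = raw$tr_out,
    outcome = c("reward", "break")[raw$tr_outcome],
    cause = ifelse(raw$tr_outcome == 2L, BREAK_CAUSES[pmax(raw$tr_cause, 1L)],
                   NA_character_),
    stringsAsFactors = FALSE)
  structure(
    list(events = events, trials = trials,
         n_rewards = raw$rewards,
         n_breaks = sum(trials$outcome == "break" &
                          trials$cause != "session_end"),
         n_interrupted = sum(trials$outcome == "break" &
                               trials$cause == "session_end"),
         scored_duration_s = raw$scored_s,
         end_cause = END_CAUSES[raw$end_cause],
         params = params, geom = geom,
         session_id = tracks$session_id, day_index = tracks$day_index,
         pair_id = tracks$pair_id, condition = tracks$condition),
    class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("Session '%s' (pair %s, day %d, %s mode)\n", x$session_id,
              x$pair_id, x$day_index, x$params$mode))
  cat(sprintf("  %d reward(s), %d break(s) in %.1f s (ended by %s)\n",
              x$n_rewards, x$n_breaks, x$scored_duration_s, x$end_cause))
  invisible(x)
}

#' @export
summary.session_result <- function(object, ...) {
  causes <- table(factor(object$trials$cause[object$trials$outcome == "break"],
                         levels = BREAK_CAUSES))
  out <- list(n_rewards = object$n_rewards,
              n_breaks = object$n_breaks,
              break_causes = causes,
              reward_times_s = object$events$t_s[object$events$event == "reward"],
              scored_duration_s = object$scored_duration_s,
              end_cause = object$end_cause)
  class(out) <- "summary.session_result"
  out
}

#' @export
print.summary.session_result <- function(x, ...) {
  cat(sprintf("%d reward(s), %d break(s), scored %.1f s (%s)\n",
              x$n_rewards, x$n_breaks, x$scored_duration_s, x$end_cause))
  if (x$n_breaks > 0) {
    cat("break causes:\n")
    print(x$break_causes)
  }
  if (length(x$reward_times_s))
    cat("reward times (s):", paste(sprintf("%.1f", x$reward_times_s),
                                   collapse = ", "), "\n")
  invisible(x)
}
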