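#' Brute-force session scorer (test oracle)
#'
#' An independent reimplementation of the scoring rules used only to
#' cross-check [run_session()] in tests. It keeps no incremental state:
#' each trial's arming instant, activity start, break instants
#' (two-zones-apart and mismatch-timeout), and reward instant are recomputed
#' from scratch by scanning the whole zone sequences with vectorised
#' searches (`which()` / `rle()`), then the earliest outcome wins with the
#' engine's tie-break order (caps, two-apart, timeout, reward).
#'
#' @inheritParams run_session
#' @return A list with `rewards`, `n_breaks` (coordination breaks:
#'   two-apart + timeout), `n_apart`, `n_timeout`, `n_interrupted` (trials
#'   open when the session ended), and `reward_times_s`.
#' @export
score_session_oracle <- function(tracks, params = engine_params(),
                                 geom = maze_geometry()) {
  if (is.na(tracks$dt_s))
    stop_validation("tracks are not on a shared grid; ",
                    "call resample_tracks() first")
  solitary <- params$mode == "solitary"
  per <- lapply(tracks$subjects, function(s) subject_track(tracks, s))
  if (length(per) != n_subjects_for_mode(params$mode))
    stop_validation("subject count does not match params$mode")
  z1 <- zone_codes(per[[1L]]$x_cm, geom)
  z2 <- if (solitary) z1 else zone_codes(per[[2L]]$x_cm, geom)
  n <- length(z1)
  dt <- tracks$dt_s
  ts <- per[[1L]]$time_s
  eps <- 1e-9

  # last sample the rules ever process: the time cap fires AT cap_idx
  cap_idx <- which(ts >= params$max_session_s - eps)[1L]
  limit <- if (is.na(cap_idx)) n else cap_idx - 1L
  # smallest mismatch-sample count that breaks (strict > max_mismatch_s)
  m_star <- floor((params$max_mismatch_s + eps) / dt) + 1L

  both_a <- z1 == 1L & z2 == 1L
  differ <- z1 != z2
  apart <- abs(z1 - z2) == 2L
  both_c <- z1 == 3L & z2 == 3L

  first_at_or_after <- function(idx, i) {
    idx <- idx[idx >= i & idx <= limit]
    if (length(idx)) idx[1L] else NA_integer_
  }
  which_both_a <- which(both_a)
  which_not_both_a <- which(!both_a)
  which_apart <- which(apart)
  which_both_c <- which(both_c)
  which_b1 <- which(z1 == 2L)
  which_b2 <- which(z2 == 2L)

  rewards <- 0L
  n_apart <- 0L
  n_timeout <- 0L
  n_interrupted <- 0L
  reward_times <- numeric(0)
  i <- 1L
  repeat {
    a_idx <- first_at_or_after(which_both_a, i)
    if (is.na(a_idx)) break
    s_idx <- first_at_or_after(which_not_both_a, a_idx + 1L)
    if (is.na(s_idx)) {  # armed but never active before the session ended
      n_interrupted <- n_interrupted + 1L
      break
    }
    apart_k <- timeout_k <- rew_k <- NA_integer_
    if (!solitary) {
      apart_k <- first_at_or_after(which_apart, s_idx)
      # mismatch timeout: first run of >= m_star consecutive differing
      # samples inside [s_idx, limit]
      d <- differ[s_idx:limit]
      r <- rle(d)
      ends <- cumsum(r$lengths)
      hit <- which(r$values & r$lengths >= m_star)
      if (length(hit)) {
        h <- hit[1L]
        run_start <- ends[h] - r$lengths[h] + 1L
        timeout_k <- s_idx + run_start + m_star - 2L
      }
    }
    fb1 <- first_at_or_after(which_b1, a_idx + 1L)
    fb2 <- if (solitary) fb1 else first_at_or_after(which_b2, a_idx + 1L)
    if (!is.na(fb1) && !is.na(fb2)) {
      lo <- max(s_idx, fb1 + 1L, fb2 + 1L)
      rew_k <- first_at_or_after(which_both_c, lo)
    }
    cand <- c(apart = apart_k, timeout = timeout_k, reward = rew_k)
    if (all(is.na(cand))) {  # active trial still open at session end
      n_interrupted <- n_interrupted + 1L
      break
    }
    # engine tie-break: two-apart beats timeout beats reward at equal index
    best <- which(cand == min(cand, na.rm = TRUE))[1L]
    out_k <- cand[[best]]
    if (names(cand)[best] == "reward") {
      rewards <- rewards + 1L
      reward_times <- c(reward_times, ts[out_k])
      if (rewards >= params$max_rewarded_trials) break  # trial cap
    } else if (names(cand)[best] == "apart") {
      n_apart <- n_apart + 1L
    } else {
      n_timeout <- n_timeout + 1L
    }
    i <- out_k + 1L
  }
  list(rewards = rewards, n_breaks = n_apart + n_timeout,
       n_apart = n_apart, n_timeout = n_timeout,
       n_interrupted = n_interrupted, reward_times_s = reward_times)
}
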