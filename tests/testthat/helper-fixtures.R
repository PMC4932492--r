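# Deterministic zone-timeline fixtures used across the engine tests.

# one A->B->C->A circuit as a timeline fragment; dwells in seconds
circuit_fragment <- function(a1 = 6, b1 = 6, c1 = 7, b2 = 3, a2 = 3) {
  list(list("A", a1), list("B", b1), list("C", c1),
       list("B", b2), list("A", a2))
}

# glued pair: both subjects run the same timeline
glued_fixture <- function(n_circuits, circuit = circuit_fragment(),
                          dt_s = 0.1) {
  tl <- do.call(c, rep(list(circuit), n_circuits))
  fixture_from_zone_timeline(list(tl, tl), dt_s = dt_s)
}

# subject 2 trails subject 1 by `lag_s` through identical circuits
trailing_fixture <- function(lag_s, n_circuits = 3, dt_s = 0.1,
                             circuit = circuit_fragment(15, 15, 15, 5, 10)) {
  lead <- do.call(c, rep(list(circuit), n_circuits))
  trail <- c(list(list("A", lag_s)), lead)
  fixture_from_zone_timeline(list(lead, trail), dt_s = dt_s)
}

# random zone timeline: `n_seg` dwells of 0.5-30 s in random zones
random_timeline <- function(n_seg, dt_s = 0.1) {
  lapply(seq_len(n_seg), function(i) {
    list(sample(c("A", "B", "C"), 1L),
         round(stats::runif(1, 0.5, 30) / dt_s) * dt_s)
  })
}

# random paired session mixing independent, identical, and lag-shifted
# partner timelines so rewards, breaks, and re-arms all get exercised
random_session <- function(dt_s = 0.1) {
  n_seg <- sample(4:16, 1L)
  tl1 <- random_timeline(n_seg, dt_s)
  u <- stats::runif(1)
  tl2 <- if (u < 0.4) {
    random_timeline(sample(4:16, 1L), dt_s)
  } else if (u < 0.7) {
    tl1
  } else {
    lag <- round(stats::runif(1, 0, 12) / dt_s) * dt_s
    if (lag > 0) c(list(list("A", lag)), tl1) else tl1
  }
  fixture_from_zone_timeline(list(tl1, tl2), dt_s = dt_s)
}

expect_engine_matches_oracle <- function(tracks,
                                         params = engine_params(),
                                         geom = maze_geometry()) {
  res <- run_session(tracks, params, geom)
  orc <- score_session_oracle(tracks, params, geom)
  expect_identical(res$n_rewards, orc$rewards)
  trial_causes <- res$trials$cause[res$trials$outcome == "break"]
  expect_identical(sum(trial_causes == "two_zones_apart"), orc$n_apart)
  expect_identical(sum(trial_causes == "mismatch_timeout"), orc$n_timeout)
  expect_identical(res$n_interrupted, orc$n_interrupted)
  expect_equal(res$events$t_s[res$events$event == "reward"],
               orc$reward_times_s)
  invisible(NULL)
}
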