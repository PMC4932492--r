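test_that("a perfectly coordinated pair is capped at 20 rewarded trials", {
  trk <- glued_fixture(30, dt_s = 0.1)  # 30 circuits of 25 s = 750 s
  res <- run_session(trk)
  expect_identical(res$n_rewards, 20L)
  expect_identical(res$end_cause, "trial_cap")
  expect_identical(sum(res$events$event == "reward"), 20L)
  expect_identical(res$n_breaks, 0L)
})

test_that("a stationary pair in zone A times out at exactly the session cap", {
  trk <- fixture_from_zone_timeline(
    list(list(list("A", 910)), list(list("A", 910))), dt_s = 0.1)
  res <- run_session(trk)
  expect_identical(res$n_rewards, 0L)
  expect_equal(res$scored_duration_s, 900)
  expect_identical(res$end_cause, "time_cap")
})

test_that("the 10 s different-zone rule is strict: 9 and 10 s lags reward, 11 s does not", {
  for (lag in c(9, 10)) {
    res <- run_session(trailing_fixture(lag))
    expect_identical(res$n_rewards, 3L)
    expect_identical(res$n_breaks, 0L)
  }
  res11 <- run_session(trailing_fixture(11))
  expect_identical(res11$n_rewards, 0L)
  expect_true(all(res11$trials$cause[res11$trials$outcome == "break"] ==
                    "mismatch_timeout"))
  expect_gt(res11$n_breaks, 0L)
})

test_that("A and C co-occupancy breaks the trial instantly", {
  # subject 1 jumps A -> C while subject 2 stays in A
  tl1 <- list(list("A", 5), list("C", 5), list("A", 5))
  tl2 <- list(list("A", 15))
  res <- run_session(fixture_from_zone_timeline(list(tl1, tl2), dt_s = 0.1))
  brk <- res$events[res$events$event == "break", ]
  expect_identical(nrow(brk), 1L)
  expect_identical(brk$detail, "two_zones_apart")
  expect_equal(brk$t_s, 5)  # the first sample of the jump
  expect_identical(res$n_rewards, 0L)
})

test_that("rewards require each subject's A-then-B-then-C progression", {
  # the pair jumps A -> C together: no B visit, no reward on the first C
  tl <- list(list("A", 5), list("C", 5), list("A", 5), list("B", 5),
             list("C", 5))
  res <- run_session(fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1))
  expect_identical(res$n_rewards, 1L)
  # the single reward comes from the second C dwell, after the B visit
  expect_gte(res$events$t_s[res$events$event == "reward"], 20)
})

test_that("subjects starting outside A cannot complete a trial before first arming", {
  # both start in B and traverse to C: no arming, no reward
  tl <- list(list("B", 5), list("C", 5))
  res <- run_session(fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1))
  expect_identical(res$n_rewards, 0L)
  expect_identical(nrow(res$trials), 0L)
  # after visiting A the same traversal rewards
  tl2 <- list(list("B", 5), list("A", 5), list("B", 5), list("C", 5))
  res2 <- run_session(fixture_from_zone_timeline(list(tl2, tl2), dt_s = 0.1))
  expect_identical(res2$n_rewards, 1L)
})

test_that("a pair never sharing a zone earns nothing", {
  tl1 <- do.call(c, rep(list(list(list("A", 10), list("B", 10))), 20))
  tl2 <- do.call(c, rep(list(list(list("B", 10), list("A", 10))), 20))
  res <- run_session(fixture_from_zone_timeline(list(tl1, tl2), dt_s = 0.1))
  expect_identical(res$n_rewards, 0L)
})

test_that("solitary mode rewards each of the subject's own A-B-C traversals", {
  n <- 5
  tl <- do.call(c, rep(list(circuit_fragment()), n))
  trk <- fixture_from_zone_timeline(list(tl), dt_s = 0.1,
                                    condition = condition_spec(mode = "solitary"))
  res <- run_session(trk, engine_params(mode = "solitary"))
  expect_identical(res$n_rewards, as.integer(n))
  expect_identical(res$n_breaks, 0L)
})

test_that("tightening the mismatch tolerance never increases rewards", {
  set.seed(421)
  for (rep in 1:5) {
    trk <- random_session()
    rewards <- vapply(c(2, 5, 8, 10, 15), function(tol)
      run_session(trk, engine_params(max_mismatch_s = tol))$n_rewards, 1L)
    expect_true(all(diff(rewards) >= 0L))  # rewards grow with tolerance
  }
})

test_that("event logs are well-ordered and respect the caps", {
  set.seed(99)
  for (rep in 1:10) {
    res <- run_session(random_session())
    expect_true(!is.unsorted(res$events$t_s))
    ends <- which(res$events$event == "session_end")
    expect_identical(ends, nrow(res$events))
    expect_lte(res$n_rewards, 20L)
    expect_lte(res$scored_duration_s, 900)
    expect_true(all(res$trials$t_armed <= res$trials$t_outcome))
  }
})

test_that("engine and brute-force oracle agree on randomized sessions", {
  set.seed(2024)
  for (rep in 1:200) expect_engine_matches_oracle(random_session())
})

test_that("scoring refuses tracks that are not on a shared grid", {
  df <- rbind(data.frame(time_s = c(0, 1, 2), subject_id = "r1",
                         x_cm = 5, y_cm = 0),
              data.frame(time_s = c(0, 1.5, 2), subject_id = "r2",
                         x_cm = 5, y_cm = 0))
  trk <- session_tracks(df)  # dt_s unknown
  expect_error(run_session(trk), "resample")
  trk$dt_s <- 1
  expect_error(run_session(trk), "resample")
})
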