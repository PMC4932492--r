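make_track_df <- function(n = 10, subjects = c("r1", "r2"), dt = 0.5) {
  do.call(rbind, lapply(subjects, function(s)
    data.frame(time_s = (seq_len(n) - 1) * dt, subject_id = s,
               x_cm = seq(0, 100, length.out = n), y_cm = 10)))
}

test_that("track files round-trip through read and write", {
  path <- withr::local_tempfile(fileext = ".csv")
  trk <- session_tracks(make_track_df(), dt_s = 0.5)
  write_tracks(trk, path)
  back <- read_tracks(path)
  expect_equal(back$data, trk$data)
  expect_identical(length(back$subjects), 2L)
})

test_that("track validation names the offence", {
  path <- withr::local_tempfile(fileext = ".csv")

  df <- make_track_df()
  names(df)[3] <- "x_position"
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_tracks(path), "missing column")

  df3 <- make_track_df(subjects = c("r1", "r2", "r3"))
  utils::write.csv(df3, path, row.names = FALSE)
  expect_error(read_tracks(path), "at most 2 subjects")

  dfneg <- make_track_df()
  dfneg$time_s[4] <- -1
  utils::write.csv(dfneg, path, row.names = FALSE)
  expect_error(read_tracks(path), "finite and >= 0")

  dfdup <- make_track_df(subjects = "r1")
  dfdup$time_s[3] <- dfdup$time_s[2]
  utils::write.csv(dfdup, path, row.names = FALSE)
  expect_error(read_tracks(path, condition_spec(mode = "solitary")),
               "strictly increasing")
})

test_that("subject count must match the condition mode", {
  expect_error(session_tracks(make_track_df(subjects = "r1")),
               "paired mode requires exactly 2")
  expect_error(session_tracks(make_track_df(),
                              condition_spec(mode = "solitary")),
               "solitary mode requires exactly 1")
})

test_that("a column mapping accommodates foreign headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- make_track_df()
  names(df) <- c("t", "animal", "posx", "posy")
  utils::write.csv(df, path, row.names = FALSE)
  trk <- read_tracks(path, col_map = c(time_s = "t", subject_id = "animal",
                                       x_cm = "posx", y_cm = "posy"))
  expect_identical(nrow(trk$data), 20L)
})

test_that("resampling is linear, idempotent on the native grid, and uses the min-of-ends rule", {
  # linearity: x(0) = 0, x(10) = 120 -> x(5) = 60
  df <- data.frame(time_s = c(0, 10), subject_id = "r1",
                   x_cm = c(0, 120), y_cm = 0)
  trk <- session_tracks(df, condition_spec(mode = "solitary"))
  res <- resample_tracks(trk, dt_s = 5, gap_warn_s = 20)
  expect_equal(res$data$x_cm, c(0, 60, 120))

  # idempotence on an already-regular grid
  trk2 <- session_tracks(make_track_df(), dt_s = 0.5)
  res2 <- resample_tracks(trk2, dt_s = 0.5)
  expect_equal(res2$data$x_cm, trk2$data$x_cm, tolerance = 1e-12)

  # shared grid ends at the earliest per-subject last timestamp
  df3 <- rbind(data.frame(time_s = seq(0, 900, 1), subject_id = "r1",
                          x_cm = 1, y_cm = 0),
               data.frame(time_s = seq(0, 905, 1), subject_id = "r2",
                          x_cm = 2, y_cm = 0))
  res3 <- resample_tracks(session_tracks(df3), dt_s = 0.1)
  expect_equal(max(res3$data$time_s), 900)

  # interpolated positions stay within the hull of their neighbours
  set.seed(7)
  df4 <- data.frame(time_s = 0:20, subject_id = "r1",
                    x_cm = runif(21, 0, 120), y_cm = runif(21, 0, 40))
  res4 <- resample_tracks(session_tracks(df4, condition_spec(mode = "solitary")),
                          dt_s = 0.25)
  expect_true(all(res4$data$x_cm >= min(df4$x_cm) - 1e-9 &
                    res4$data$x_cm <= max(df4$x_cm) + 1e-9))
})

test_that("long tracking gaps are interpolated with a warning", {
  df <- data.frame(time_s = c(0, 0.5, 5, 5.5), subject_id = "r1",
                   x_cm = c(0, 10, 100, 110), y_cm = 0)
  trk <- session_tracks(df, condition_spec(mode = "solitary"))
  expect_warning(resample_tracks(trk, dt_s = 0.5), "gap")
})

test_that("event logs round-trip in both formats and rewards carry pump fields", {
  trk <- glued_fixture(2)
  res <- run_session(trk)
  for (fmt in c("csv", "jsonl")) {
    path <- withr::local_tempfile()
    write_events(res$events, path, format = fmt)
    back <- read_events(path, format = fmt)
    expect_equal(back, res$events, tolerance = 1e-9)
  }
  rewards <- res$events[res$events$event == "reward", ]
  expect_true(nrow(rewards) >= 1)
  expect_true(all(rewards$reward_volume_ul == 70))
  expect_true(all(rewards$pump_duration_s == 1.5))

  # empty log -> header-only file
  path <- withr::local_tempfile()
  write_events(coopmaze:::empty_event_log(), path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_events(path)), 0L)
})

test_that("zone-timeline fixtures reproduce their timeline exactly", {
  trk <- fixture_from_zone_timeline(list(list("A", 5)), dt_s = 0.1)
  expect_identical(unique(zone_of(trk$data$x_cm)), "A")

  tl <- list(list("A", 5), list("B", 5), list("C", 5))
  trk2 <- fixture_from_zone_timeline(list(tl, tl), dt_s = 0.1)
  d1 <- trk2$data[trk2$data$subject_id == "rat1", ]
  z <- zone_of(d1$x_cm)
  expect_identical(rle(z)$values, c("A", "B", "C"))
  expect_identical(rle(z)$lengths, rep(50L, 3))
  expect_equal(d1$time_s[which(z == "B")[1]], 5)
  expect_equal(d1$time_s[which(z == "C")[1]], 10)

  expect_error(fixture_from_zone_timeline(list(list("D", 5))), "unknown zone")
  expect_error(fixture_from_zone_timeline(list(list("A", 0.55)), dt_s = 0.1),
               "multiple")
})
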