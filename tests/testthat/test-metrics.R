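test_that("path length sums Euclidean steps and is 0 for degenerate tracks", {
  expect_warning(l0 <- path_length(data.frame(x_cm = 5, y_cm = 5)), "fewer")
  expect_identical(l0, 0)
  stationary <- data.frame(x_cm = rep(5, 50), y_cm = rep(10, 50))
  expect_identical(path_length(stationary), 0)
  straight <- data.frame(x_cm = seq(0, 120, 1), y_cm = 0)
  expect_equal(path_length(straight), 120)
  out_back <- data.frame(x_cm = c(seq(0, 120, 1), seq(119, 0, -1)), y_cm = 0)
  expect_equal(path_length(out_back), 240)
})

test_that("path length is time-reversal invariant and additive", {
  set.seed(11)
  for (rep in 1:10) {
    trk <- data.frame(x_cm = runif(200, 0, 120), y_cm = runif(200, 0, 40))
    expect_equal(path_length(trk), path_length(trk[nrow(trk):1, ]))
    cut <- sample(2:199, 1)
    expect_equal(path_length(trk),
                 path_length(trk[1:cut, ]) +
                   path_length(trk[cut:nrow(trk), ]))
  }
})

test_that("session metrics compute the efficacy index and latency", {
  trk <- glued_fixture(5, dt_s = 0.1)
  res <- run_session(trk)
  m <- session_metrics(res, trk)
  expect_identical(m$rewards, res$n_rewards)
  expect_equal(m$activity_cm, m$activity_1_cm + m$activity_2_cm)
  expect_equal(m$efficacy * m$activity_cm, m$rewards)
  # first pair C arrival completes a valid trial here, so latency equals
  # the oracle's first reward instant
  orc <- score_session_oracle(trk)
  expect_equal(m$latency_s, orc$reward_times_s[1])
  m2 <- session_metrics(res, trk, latency = "first_reward")
  expect_equal(m2$latency_s, orc$reward_times_s[1])
  expect_lte(m$latency_s, m$scored_duration_s)
})

test_that("a stationary session yields zero metrics and censored latency", {
  trk <- fixture_from_zone_timeline(
    list(list(list("A", 60)), list(list("A", 60))), dt_s = 0.1)
  res <- run_session(trk)
  m <- session_metrics(res, trk)
  expect_identical(m$rewards, 0L)
  expect_identical(m$activity_cm, 0)
  expect_identical(m$efficacy, 0)  # 0-activity convention
  expect_true(is.na(m$latency_s))
})

test_that("metric rows satisfy efficacy x activity = rewards on simulated sessions", {
  rows <- simulate_experiment(
    experiment_plan(n_pairs = 2, days = 3, latent_days = 0, seed = 5,
                    scenario_defaults = list(session_s = 300)))
  expect_identical(nrow(rows), 6L)
  nz <- rows$activity_cm > 0
  expect_equal(rows$efficacy[nz] * rows$activity_cm[nz],
               as.numeric(rows$rewards[nz]))
})

test_that("session ids must match between result and tracks", {
  trk <- glued_fixture(2)
  res <- run_session(trk)
  trk2 <- trk
  trk2$session_id <- "other"
  expect_error(session_metrics(res, trk2), "session ids differ")
})

test_that("day aggregation reports mean, SEM and n, excluding censored latencies", {
  row <- function(pair, day, rewards, lat) {
    data.frame(pair_id = pair, day_index = day, condition = "c",
               rewards = rewards, activity_cm = 100 * rewards,
               efficacy = ifelse(rewards > 0, 0.01, 0), latency_s = lat)
  }
  rows <- rbind(row("p1", 1, 4, 30), row("p2", 1, 6, NA),
                row("p1", 2, 10, 12), row("p2", 2, 12, 18))
  tab <- aggregate_days(rows)
  d1 <- tab[tab$day_index == 1, ]
  expect_equal(d1$rewards_mean, 5)
  expect_equal(d1$rewards_sem, 1)  # sd(c(4,6))/sqrt(2)
  expect_identical(d1$rewards_n, 2L)
  expect_identical(d1$latency_s_n, 1L)  # censored excluded
  expect_equal(d1$latency_s_mean, 30)
  expect_true(is.na(d1$latency_s_sem))  # n = 1

  # permutation invariance
  tab2 <- aggregate_days(rows[sample(nrow(rows)), ])
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  # empty input -> empty table
  expect_identical(nrow(aggregate_days(rows[0, ])), 0L)
})

test_that("aggregation at the published scale yields one row per day per metric", {
  rows <- expand.grid(pair_id = sprintf("p%02d", 1:11), day_index = 1:18)
  rows$condition <- "c"
  set.seed(3)
  rows$rewards <- rpois(nrow(rows), 10)
  rows$activity_cm <- runif(nrow(rows), 5000, 9000)
  rows$efficacy <- rows$rewards / rows$activity_cm
  rows$latency_s <- runif(nrow(rows), 10, 100)
  tab <- aggregate_days(rows)
  expect_identical(nrow(tab), 18L)
  expect_true(all(tab$rewards_n == 11L))
})

test_that("percent change follows the reduction convention with propagated SEM", {
  row <- function(day, lat) data.frame(pair_id = c("a", "b"), day_index = day,
                                       condition = "c", rewards = 1,
                                       activity_cm = 1, efficacy = 1,
                                       latency_s = lat)
  tab <- aggregate_days(rbind(row(1, c(99, 101)), row(8, c(17.0, 17.8))))
  pc <- percent_change(tab, "latency_s", baseline_day = 1)
  expect_equal(pc$pct_change[pc$day_index == 1], 0)
  expect_equal(pc$pct_change_sem[pc$day_index == 1], 0)
  # 100 -> 17.4 is an 82.6% reduction
  expect_equal(pc$pct_change[pc$day_index == 8], 82.6)
  expect_gt(pc$pct_change_sem[pc$day_index == 8], 0)

  # flat curve -> flat 0%
  flat <- aggregate_days(rbind(row(1, c(50, 50)), row(2, c(50, 50))))
  expect_equal(percent_change(flat, "latency_s")$pct_change, c(0, 0))

  # zero baseline is an error
  zero <- aggregate_days(rbind(row(1, c(0, 0)), row(2, c(10, 10))))
  expect_error(percent_change(zero, "latency_s"), "baseline")
})
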