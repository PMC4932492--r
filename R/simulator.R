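#' Parameters of one simulated agent
#'
#' The simulator models each rat as a one-dimensional shuttling agent on the
#' maze's longitudinal axis: a drift toward its current goal wall (the C
#' wall while seeking reward, the A wall while returning), a saturating
#' attraction toward its partner's position, and Ornstein-Uhlenbeck velocity
#' noise. Learning is an exponential saturation of the goal drive and the
#' partner coupling across days, per individual.
#'
#' @param speed_cm_s Mean full-drive progression speed (cm/s).
#' @param noise_sd Stationary SD of the velocity noise (cm/s).
#' @param goal_gain Day-1 goal drive, fraction of `speed_cm_s` in `[0, 1]`.
#' @param goal_gain_asym Asymptotic goal drive after learning.
#' @param coupling Day-1 attraction strength toward the partner, in `[0, 1]`.
#' @param coupling_asym Asymptotic coupling after learning.
#' @param learn_rate Per-day rate of the exponential saturation (1/day).
#' @param drink_pause_s Dwell at the C wall after arriving (drinking), s.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(speed_cm_s = 6.5, noise_sd = 5,
                         goal_gain = 0.12, goal_gain_asym = 0.95,
                         coupling = 0.15, coupling_asym = 0.9,
                         learn_rate = 0.15, drink_pause_s = 8) {
  if (speed_cm_s < 0 || noise_sd < 0 || drink_pause_s < 0)
    stop_validation("speeds, noise and pauses must be >= 0")
  for (v in c(goal_gain, goal_gain_asym, coupling, coupling_asym))
    if (v < 0 || v > 1)
      stop_validation("goal_gain and coupling values must lie in [0, 1]")
  if (learn_rate < 0) stop_validation("learn_rate must be >= 0")
  structure(list(speed_cm_s = speed_cm_s, noise_sd = noise_sd,
                 goal_gain = goal_gain, goal_gain_asym = goal_gain_asym,
                 coupling = coupling, coupling_asym = coupling_asym,
                 learn_rate = learn_rate, drink_pause_s = drink_pause_s),
            class = "agent_params")
}

# exponential-saturation learning curve: value on a given training day
learned_value <- function(v0, v_asym, rate, day) {
  v_asym - (v_asym - v0) * exp(-rate * (day - 1))
}

DEFAULT_DIVIDER_MULTIPLIERS <- c(sealed = 0.4, perforated = 0.35,
                                 transparent = 0.7,
                                 transparent_perforated = 1.0)
DEFAULT_SEX_SPEED_MULTIPLIERS <- c(female = 1.25, male = 1.0,
                                   unspecified = 1.0)

#' Simulation scenario for one pair (or one solitary agent)
#'
#' Collects the agents, condition, and coupling modifiers for a simulated
#' session. The effective coupling of an agent on a given day is
#' `coupling(day) * familiarity * divider multiplier * (1 - context
#' penalty)`: the divider controls which sensory channels connect the
#' partners (multipliers encode only the observed ordering of divider
#' conditions, full-modality best, not measured effect sizes), contextual
#' wall cues divert attention from the partner (a coupling penalty, not a
#' speed penalty, so rewards drop while activity is spared), and
#' familiarity is the pair-specific attunement that grows with days spent
#' with the current partner (see [simulate_experiment()]).
#'
#' @param agent1,agent2 [agent_params()] for the two subjects (`agent2`
#'   ignored in solitary mode).
#' @param condition A [condition_spec()].
#' @param divider_coupling_multiplier Named multipliers in `(0, 1]`, one per
#'   divider type.
#' @param context_coupling_penalty Coupling fraction lost to contextual
#'   cues, in `[0, 1)`. Applied only when `condition$context_cues`.
#' @param sex_speed_multiplier Named speed multipliers by sex label; the
#'   stylised sex arm acts through locomotor speed only.
#' @param session_s Simulated session length (s). Default 900.
#' @param dt_s Sampling interval of the emulated tracker (s). Default 0.04
#'   (25 Hz).
#' @param familiarity Pair-familiarity factor in `[0, 1]` scaling coupling.
#' @param sat_cm Separation scale of the saturating partner attraction.
#' @param rearm_pause_s Dwell at the A wall before heading out again (s).
#' @param arrive_tol_cm Distance from a wall that counts as arrival (cm).
#' @param noise_tau_s Relaxation time of the velocity noise (s).
#' @param start_x_cm Starting longitudinal position (cm, inside zone A).
#' @param seed Scenario seed; sessions are reproducible from `(seed, day)`.
#' @return An object of class `pair_scenario`.
#' @export
pair_scenario <- function(agent1 = agent_params(), agent2 = agent_params(),
                          condition = condition_spec(),
                          divider_coupling_multiplier = DEFAULT_DIVIDER_MULTIPLIERS,
                          context_coupling_penalty = 0.35,
                          sex_speed_multiplier = DEFAULT_SEX_SPEED_MULTIPLIERS,
                          session_s = 900, dt_s = 0.04, familiarity = 1,
                          sat_cm = 25, rearm_pause_s = 2, arrive_tol_cm = 3,
                          noise_tau_s = 0.5, start_x_cm = 5, seed = 1L) {
  if (!all(DIVIDER_TYPES %in% names(divider_coupling_multiplier)))
    stop_validation("divider_coupling_multiplier must name all divider types")
  dm <- divider_coupling_multiplier[DIVIDER_TYPES]
  if (any(dm <= 0 | dm > 1))
    stop_validation("divider multipliers must lie in (0, 1]")
  if (context_coupling_penalty < 0 || context_coupling_penalty >= 1)
    stop_validation("context_coupling_penalty must lie in [0, 1)")
  if (session_s <= 0 || dt_s <= 0)
    stop_validation("session_s and dt_s must be positive")
  if (familiarity < 0 || familiarity > 1)
    stop_validation("familiarity must lie in [0, 1]")
  structure(list(agents = list(agent1, agent2), condition = condition,
                 divider_coupling_multiplier = dm,
                 context_coupling_penalty = context_coupling_penalty,
                 sex_speed_multiplier = sex_speed_multiplier,
                 session_s = session_s, dt_s = dt_s,
                 familiarity = familiarity, sat_cm = sat_cm,
                 rearm_pause_s = rearm_pause_s,
                 arrive_tol_cm = arrive_tol_cm, noise_tau_s = noise_tau_s,
                 start_x_cm = start_x_cm, seed = as.integer(seed)),
            class = "pair_scenario")
}

# deterministic substream seed below 2^31 from up to three labels
mix_seed <- function(a, b = 0, c = 0) {
  m <- 2147483629
  s <- (as.numeric(a) %% m)
  s <- (s * 1000003 + as.numeric(b) * 10007 + as.numeric(c) * 101 + 12345) %% m
  as.integer(s) + 1L
}

simulate_tracks <- function(scenario, day, n_agents, mode) {
  dt <- scenario$dt_s
  n_steps <- round(scenario$session_s / dt) + 1L  # includes t = session_s
  cond <- scenario$condition
  spd_mult <- scenario$sex_speed_multiplier[[cond$sex]]
  div_mult <- scenario$divider_coupling_multiplier[[cond$divider]]
  ctx <- if (isTRUE(cond$context_cues)) 1 - scenario$context_coupling_penalty else 1
  ag <- scenario$agents[seq_len(n_agents)]
  speed <- vapply(ag, function(p) p$speed_cm_s * spd_mult, 1)
  noise <- vapply(ag, function(p) p$noise_sd, 1)
  gday <- vapply(ag, function(p)
    learned_value(p$goal_gain, p$goal_gain_asym, p$learn_rate, day), 1)
  cday <- vapply(ag, function(p)
    learned_value(p$coupling, p$coupling_asym, p$learn_rate, day), 1)
  c_eff <- if (n_agents == 2L)
    cday * scenario$familiarity * div_mult * ctx else rep(0, n_agents)
  drink <- vapply(ag, function(p) p$drink_pause_s, 1)
  geom <- maze_geometry()
  set.seed(mix_seed(scenario$seed, day))
  X <- simulate_agents_cpp(n_steps, dt, geom$length_cm, speed, noise,
                           scenario$noise_tau_s, gday, c_eff,
                           scenario$sat_cm, drink, scenario$rearm_pause_s,
                           scenario$arrive_tol_cm,
                           rep(scenario$start_x_cm, n_agents))
  lane_y <- lane_centres(geom)
  df <- do.call(rbind, lapply(seq_len(n_agents), function(j) {
    data.frame(time_s = (seq_len(n_steps) - 1L) * dt,
               subject_id = paste0("rat", j),
               x_cm = X[, j],
               y_cm = lane_y[min(j, length(lane_y))])
  }))
  session_tracks(df, condition = cond, dt_s = dt,
                 session_id = sprintf("sim_day%02d_seed%d", day, scenario$seed),
                 day_index = day, pair_id = "simpair")
}

#' Simulate one paired session
#'
#' Generates emulated tracker output for one session of a pair of coupled
#' agents on a given training day. Bit-identical tracks are produced for
#' the same `(scenario$seed, day)`.
#'
#' @param scenario A [pair_scenario()] (its condition must be paired mode).
#' @param day Training day (drives the learned goal drive and coupling).
#' @return A [session_tracks()] object on the simulator grid.
#' @examples
#' scn <- pair_scenario(seed = 7)
#' trk <- simulate_session(scn, day = 18)
#' run_session(trk, engine_params())
#' @export
simulate_session <- function(scenario, day = 1L) {
  if (scenario$condition$mode != "paired")
    stop_validation("scenario condition is not paired mode; ",
                    "use simulate_solitary()")
  simulate_tracks(scenario, day, 2L, "paired")
}

#' Simulate one solitary session
#'
#' Single-agent variant: the partner coupling is ignored; the agent simply
#' shuttles between the walls under its own goal drive and noise.
#'
#' @param scenario A [pair_scenario()] whose condition is solitary mode
#'   (only `agent1` is used).
#' @param day Training day.
#' @return A [session_tracks()] object with one subject.
#' @export
simulate_solitary <- function(scenario, day = 1L) {
  if (scenario$condition$mode != "solitary")
    stop_validation("scenario condition must be solitary mode")
  simulate_tracks(scenario, day, 1L, "solitary")
}
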