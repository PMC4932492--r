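#' Plan a multi-pair, multi-day simulated experiment
#'
#' Describes an experimental arm at the assay's published scale: a cohort
#' of pairs trained daily, optionally followed by a latent-learning phase in
#' which one partner of each pair is replaced by another trained partner on
#' `swap_day`.
#'
#' @param n_pairs Number of pairs (solitary mode: number of single agents).
#' @param days Length of the initial learning phase (days).
#' @param latent_days Additional days after the partner swap (0 disables the
#'   swap).
#' @param swap_day Day of the partner replacement; defaults to `days + 1`
#'   when `latent_days > 0`.
#' @param condition A [condition_spec()] shared by the whole arm.
#' @param agent Baseline [agent_params()] for the cohort; individual agents
#'   jitter around it (see [simulate_experiment()]).
#' @param params [engine_params()] used to score each simulated session
#'   (its mode is forced to the condition's mode).
#' @param scenario_defaults Named list overriding [pair_scenario()] fields
#'   (e.g. `session_s`, `dt_s`, multipliers).
#' @param seed Master seed; every session is reproducible from it.
#' @return An object of class `experiment_plan`.
#' @export
experiment_plan <- function(n_pairs = 11, days = 18, latent_days = 6,
                            swap_day = NULL, condition = condition_spec(),
                            agent = agent_params(),
                            params = engine_params(),
                            scenario_defaults = list(), seed = 1L) {
  if (n_pairs < 1 || days < 1 || latent_days < 0)
    stop_validation("n_pairs and days must be >= 1, latent_days >= 0")
  total <- days + latent_days
  if (is.null(swap_day) && latent_days > 0) swap_day <- days + 1L
  if (!is.null(swap_day) && (swap_day < 2L || swap_day > total))
    stop_validation("swap_day must lie within the day range 2..", total)
  if (!is.null(swap_day) && condition$mode == "solitary")
    stop_validation("partner swap is meaningless in solitary mode")
  structure(list(n_pairs = as.integer(n_pairs), days = as.integer(days),
                 latent_days = as.integer(latent_days),
                 swap_day = if (is.null(swap_day)) NA_integer_ else
                   as.integer(swap_day),
                 condition = condition, agent = agent, params = params,
                 scenario_defaults = scenario_defaults,
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("Experiment plan: %d pair(s), %d + %d day(s)%s, seed %d\n",
              x$n_pairs, x$days, x$latent_days,
              if (!is.na(x$swap_day))
                sprintf(", partner swap on day %d", x$swap_day) else "",
              x$seed))
  print(x$condition)
  invisible(x)
}

# individual agents jitter around the cohort baseline so pairs differ and a
# swapped-in partner is genuinely a different animal
draw_agents <- function(base, n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    p <- base
    p$speed_cm_s <- base$speed_cm_s * exp(rnorm(1, 0, 0.15))
    p$learn_rate <- base$learn_rate * exp(rnorm(1, 0, 0.15))
    p$coupling_asym <- min(1, max(0, base$coupling_asym + rnorm(1, 0, 0.03)))
    p$goal_gain_asym <- min(1, max(0, base$goal_gain_asym + rnorm(1, 0, 0.02)))
    p
  })
}

# pair-familiarity: attunement to the current partner, saturating with days
# already spent together (0 on their first day as a pair)
FAMILIARITY_FLOOR <- 0.35
FAMILIARITY_RATE <- 0.25
familiarity_factor <- function(days_together) {
  FAMILIARITY_FLOOR + (1 - FAMILIARITY_FLOOR) *
    (1 - exp(-FAMILIARITY_RATE * days_together))
}

#' Simulate and score a whole experimental arm
#'
#' Runs every pair of the plan through every day: simulates the session,
#' scores it with [run_session()], and computes [session_metrics()]. Agents
#' are individuals: their learned goal drive and coupling depend on their
#' own accumulated training days and persist across the partner swap
#' (partners change, skills do not), while the pair-familiarity component
#' of coupling restarts at its floor for the new pairing — so the
#' latent-learning signature (a day-`swap_day` dip that stays well above
#' day 1 and recovers quickly) is an emergent consequence of the model, not
#' a hard-coded day effect. The swap rotates the second member of each pair
#' to the next pair, so every rat receives a trained but unfamiliar
#' partner.
#'
#' @param plan An [experiment_plan()].
#' @return Data frame of metric rows, one per pair per day (see
#'   [session_metrics()]), ready for [aggregate_days()].
#' @examples
#' \donttest{
#' plan <- experiment_plan(n_pairs = 3, days = 4, latent_days = 0, seed = 42)
#' rows <- simulate_experiment(plan)
#' aggregate_days(rows)
#' }
#' @export
simulate_experiment <- function(plan) {
  if (!inherits(plan, "experiment_plan"))
    stop_validation("plan must be an experiment_plan object")
  solitary <- plan$condition$mode == "solitary"
  n_agents <- if (solitary) plan$n_pairs else 2L * plan$n_pairs
  agents <- draw_agents(plan$agent, n_agents, mix_seed(plan$seed, 0, 99))
  # partner assignment: pair i starts with agents (2i-1, 2i)
  second_of <- if (solitary) rep(NA_integer_, plan$n_pairs) else
    2L * seq_len(plan$n_pairs)
  days_together <- rep(0L, plan$n_pairs)
  total <- plan$days + plan$latent_days
  params <- plan$params
  params$mode <- plan$condition$mode
  rows <- vector("list", plan$n_pairs * total)
  r <- 0L
  for (day in seq_len(total)) {
    if (!solitary && !is.na(plan$swap_day) && day == plan$swap_day) {
      second_of <- second_of[c(seq_len(plan$n_pairs)[-1L], 1L)]
      days_together[] <- 0L
    }
    for (i in seq_len(plan$n_pairs)) {
      a1 <- agents[[if (solitary) i else 2L * i - 1L]]
      a2 <- if (solitary) a1 else agents[[second_of[i]]]
      scn_args <- utils::modifyList(
        list(agent1 = a1, agent2 = a2, condition = plan$condition,
             familiarity = if (solitary) 1 else
               familiarity_factor(days_together[i]),
             seed = mix_seed(plan$seed, i, 7)),
        plan$scenario_defaults)
      scn <- do.call(pair_scenario, scn_args)
      trk <- if (solitary) simulate_solitary(scn, day) else
        simulate_session(scn, day)
      trk$pair_id <- sprintf("pair%02d", i)
      trk$session_id <- sprintf("%s_d%02d_p%02d",
                                plan$condition$divider, day, i)
      res <- run_session(trk, params)
      r <- r + 1L
      rows[[r]] <- session_metrics(res, trk)
    }
    days_together <- days_together + 1L
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
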