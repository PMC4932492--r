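#' Read an engine/maze configuration file
#'
#' A single plain-text YAML file with flat keys mirroring the
#' [maze_geometry()] and [engine_params()] fields (e.g. `length_cm`,
#' `zone_bounds_cm`, `max_mismatch_s`, `mode`, ...). Every default is
#' overridable; unknown keys are rejected so typos do not silently fall
#' back to defaults.
#'
#' @param path Path to the config file (`NULL` returns all defaults).
#' @return List with elements `geom` ([maze_geometry()]), `params`
#'   ([engine_params()]), and `condition` ([condition_spec()]).
#' @export
read_engine_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_validation("config file not found: ", path)
    out <- yaml::read_yaml(path)
    if (is.null(out)) list() else out
  }
  geom_keys <- names(formals(maze_geometry))
  par_keys <- names(formals(engine_params))
  cond_keys <- names(formals(condition_spec))
  unknown <- setdiff(names(cfg), c(geom_keys, par_keys, cond_keys))
  if (length(unknown))
    stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  shared <- intersect(names(cfg), "mode")
  list(geom = do.call(maze_geometry, cfg[intersect(names(cfg), geom_keys)]),
       params = do.call(engine_params,
                        cfg[intersect(names(cfg), c(par_keys))]),
       condition = do.call(condition_spec,
                           cfg[intersect(names(cfg), cond_keys)]))
}

#' Read a simulation plan file
#'
#' Flat-key YAML describing an [experiment_plan()]: `n_pairs`, `days`,
#' `latent_days`, `swap_day`, `seed`, the condition fields (`divider`,
#' `context_cues`, `sex`, `mode`), [agent_params()] fields, and
#' [pair_scenario()] overrides (`session_s`, `dt_s`, ...).
#'
#' @param path Path to the plan file.
#' @param seed Optional seed overriding the file's (e.g. from the CLI).
#' @return An [experiment_plan()].
#' @export
read_plan <- function(path, seed = NULL) {
  if (!file.exists(path)) stop_validation("plan file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  plan_keys <- c("n_pairs", "days", "latent_days", "swap_day", "seed")
  cond_keys <- names(formals(condition_spec))
  agent_keys <- names(formals(agent_params))
  scn_keys <- setdiff(names(formals(pair_scenario)),
                      c("agent1", "agent2", "condition", "seed"))
  unknown <- setdiff(names(cfg), c(plan_keys, cond_keys, agent_keys, scn_keys))
  if (length(unknown))
    stop_validation("unknown plan key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(seed)) cfg$seed <- seed
  args <- cfg[intersect(names(cfg), plan_keys)]
  args$condition <- do.call(condition_spec,
                            cfg[intersect(names(cfg), cond_keys)])
  args$agent <- do.call(agent_params,
                        cfg[intersect(names(cfg), agent_keys)])
  args$scenario_defaults <- cfg[intersect(names(cfg), scn_keys)]
  do.call(experiment_plan, args)
}
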