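#' Maze geometry
#'
#' Describes the physical maze and its virtual longitudinal partition. The
#' apparatus is a 40 cm wide, 120 cm long box split lengthwise into two
#' lanes; three virtual zones (A = start third, B = middle, C = reward end)
#' cut both lanes perpendicularly. Zone assignment depends only on the
#' longitudinal coordinate; the lateral coordinate and lane identity are
#' carried through I/O but never scored.
#'
#' Boundaries follow a half-open, lower-inclusive convention: a sample
#' sitting exactly on a boundary belongs to the farther zone, and zone C is
#' closed at the far wall, so "arrival" at a zone is unambiguous. The
#' boundary positions default to equal thirds; they are configurable because
#' only the three-zone structure, not the boundary placement, is fixed by
#' the assay.
#'
#' @param length_cm Longitudinal extent of the maze (cm).
#' @param width_cm Transverse extent (cm).
#' @param n_lanes Number of lanes (the divider runs longitudinally).
#' @param zone_bounds_cm Two ascending interior boundaries partitioning
#'   `[0, length_cm]` into zones A, B, C.
#' @param hysteresis_cm Optional boundary hysteresis width (cm). With a
#'   positive width, a tracked subject only changes zone once it has moved
#'   `hysteresis_cm / 2` beyond a boundary, which suppresses tracker jitter
#'   oscillating across a line. Default 0 (no hysteresis).
#' @return An object of class `maze_geometry`.
#' @examples
#' geom <- maze_geometry()
#' zone_of(c(0, 39.9, 40, 80, 120), geom)
#' @export
maze_geometry <- function(length_cm = 120, width_cm = 40, n_lanes = 2,
                          zone_bounds_cm = c(40, 80), hysteresis_cm = 0) {
  if (!is.numeric(length_cm) || length(length_cm) != 1L || length_cm <= 0)
    stop_validation("length_cm must be a single positive number")
  if (!is.numeric(width_cm) || length(width_cm) != 1L || width_cm <= 0)
    stop_validation("width_cm must be a single positive number")
  if (!is.numeric(zone_bounds_cm) || length(zone_bounds_cm) != 2L)
    stop_validation("zone_bounds_cm must be two interior boundaries")
  if (!(0 < zone_bounds_cm[1] && zone_bounds_cm[1] < zone_bounds_cm[2] &&
        zone_bounds_cm[2] < length_cm))
    stop_validation(
      "zone boundaries must satisfy 0 < b1 < b2 < length_cm (got ",
      zone_bounds_cm[1], ", ", zone_bounds_cm[2], " in [0, ", length_cm, "])")
  if (!is.numeric(hysteresis_cm) || hysteresis_cm < 0)
    stop_validation("hysteresis_cm must be >= 0")
  structure(
    list(length_cm = as.numeric(length_cm),
         width_cm = as.numeric(width_cm),
         n_lanes = as.integer(n_lanes),
         zone_bounds_cm = as.numeric(zone_bounds_cm),
         hysteresis_cm = as.numeric(hysteresis_cm)),
    class = "maze_geometry")
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf("Maze geometry: %.0f cm x %.0f cm, %d lanes\n",
              x$length_cm, x$width_cm, x$n_lanes))
  cat(sprintf("  zones: A [0, %g) | B [%g, %g) | C [%g, %g]\n",
              x$zone_bounds_cm[1], x$zone_bounds_cm[1], x$zone_bounds_cm[2],
              x$zone_bounds_cm[2], x$length_cm))
  if (x$hysteresis_cm > 0)
    cat(sprintf("  boundary hysteresis: %g cm\n", x$hysteresis_cm))
  invisible(x)
}

ZONE_LABELS <- c("A", "B", "C")

#' Map a longitudinal coordinate to its maze zone
#'
#' Vectorised. A coordinate below the first boundary is in zone A, between
#' the boundaries zone B, at or beyond the second boundary zone C; zone C is
#' closed at the far wall (`x == length_cm` is C).
#'
#' @param x_cm Longitudinal coordinate(s), cm, in `[0, length_cm]`.
#' @param geom A [maze_geometry()].
#' @return Character vector of zone labels in `c("A", "B", "C")`.
#' @export
zone_of <- function(x_cm, geom = maze_geometry()) {
  bad <- which(!is.finite(x_cm) | x_cm < 0 | x_cm > geom$length_cm)
  if (length(bad))
    stop_validation("coordinate outside the maze [0, ", geom$length_cm,
                    "] at sample(s) ", paste(utils::head(bad, 5L), collapse = ", "),
                    " (x = ", paste(signif(x_cm[utils::head(bad, 5L)], 4), collapse = ", "), ")")
  ZONE_LABELS[findInterval(x_cm, geom$zone_bounds_cm) + 1L]
}

# Integer zone codes 1/2/3 for A/B/C; hysteresis requires sequential state,
# so a loop runs only when hysteresis_cm > 0.
zone_codes <- function(x_cm, geom) {
  raw <- findInterval(x_cm, geom$zone_bounds_cm) + 1L
  h <- geom$hysteresis_cm / 2
  if (h <= 0 || length(x_cm) < 2L) {
    bad <- which(!is.finite(x_cm) | x_cm < 0 | x_cm > geom$length_cm)
    if (length(bad))
      stop_validation("coordinate outside the maze at sample ", bad[1L])
    return(raw)
  }
  lo <- geom$zone_bounds_cm - h  # crossing down requires x < lo
  hi <- geom$zone_bounds_cm + h  # crossing up requires x >= hi
  z <- integer(length(x_cm))
  cur <- raw[1L]
  z[1L] <- cur
  for (k in 2:length(x_cm)) {
    x <- x_cm[k]
    if (cur < 3L && x >= hi[cur]) cur <- cur + 1L
    if (cur > 1L && x < lo[cur - 1L]) cur <- cur - 1L
    z[k] <- cur
  }
  z
}

#' Ordinal distance between two maze zones
#'
#' Zones are ordered A < B < C along the maze; the distance is the number of
#' zone steps between them (A-C is 2, the configuration that instantly
#' breaks a trial).
#'
#' @param z1,z2 Zone labels in `c("A", "B", "C")` (vectorised, recycled).
#' @return Integer vector of distances in `0:2`.
#' @export
zone_distance <- function(z1, z2) {
  i1 <- match(z1, ZONE_LABELS)
  i2 <- match(z2, ZONE_LABELS)
  if (anyNA(i1) || anyNA(i2))
    stop_validation("invalid zone label; expected one of A, B, C")
  abs(i1 - i2)
}

#' Engine rule constants
#'
#' The scoring rules of the assay: a pair earns a mutual reward by moving
#' A-to-B-to-C coordinately and arriving together at zone C; occupying
#' different zones for more than `max_mismatch_s` seconds (strictly), or
#' being more than one zone apart (A and C), breaks the trial; a session
#' ends after `max_rewarded_trials` rewarded trials or `max_session_s`
#' seconds, whichever comes first. Each reward activates both pumps for
#' `pump_duration_s` seconds delivering `reward_volume_ul` microlitres of
#' 20% sucrose per rat.
#'
#' @param max_mismatch_s Continuous different-zone tolerance (s). Default 10.
#' @param max_rewarded_trials Session trial cap. Default 20.
#' @param max_session_s Session time cap (s). Default 900 (15 min).
#' @param reward_volume_ul Per-rat reward volume (microlitres). Default 70.
#' @param pump_duration_s Pump activation per reward (s). Default 1.5.
#' @param mode `"paired"` (two subjects, coordination rules enforced) or
#'   `"solitary"` (one subject; success is its own A-B-C traversal and
#'   re-arming its own return to A).
#' @return An object of class `engine_params`.
#' @export
engine_params <- function(max_mismatch_s = 10, max_rewarded_trials = 20,
                          max_session_s = 900, reward_volume_ul = 70,
                          pump_duration_s = 1.5,
                          mode = c("paired", "solitary")) {
  mode <- match.arg(mode)
  num <- c(max_mismatch_s = max_mismatch_s,
           max_rewarded_trials = max_rewarded_trials,
           max_session_s = max_session_s,
           reward_volume_ul = reward_volume_ul,
           pump_duration_s = pump_duration_s)
  if (any(!is.finite(num)) || any(num <= 0))
    stop_validation("all engine parameters must be strictly positive")
  if (max_session_s < max_mismatch_s)
    stop_validation("max_session_s must be at least max_mismatch_s")
  structure(
    list(max_mismatch_s = as.numeric(max_mismatch_s),
         max_rewarded_trials = as.integer(max_rewarded_trials),
         max_session_s = as.numeric(max_session_s),
         reward_volume_ul = as.numeric(reward_volume_ul),
         pump_duration_s = as.numeric(pump_duration_s),
         mode = mode),
    class = "engine_params")
}

#' @export
print.engine_params <- function(x, ...) {
  cat("Engine parameters (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  mismatch tolerance : %g s (strictly more breaks the trial)\n",
              x$max_mismatch_s))
  cat(sprintf("  session caps       : %d rewarded trials / %g s\n",
              x$max_rewarded_trials, x$max_session_s))
  cat(sprintf("  reward             : %g ul sucrose, pump %g s\n",
              x$reward_volume_ul, x$pump_duration_s))
  invisible(x)
}

DIVIDER_TYPES <- c("sealed", "perforated", "transparent",
                   "transparent_perforated")

#' Experimental condition of a session
#'
#' Records which arm of the assay a session belongs to: the lane divider
#' (which sensory modalities connect the two subjects), whether supplemental
#' contextual wall cues are present, the sex of the pair, and paired versus
#' solitary mode.
#'
#' @param divider One of `"sealed"`, `"perforated"`, `"transparent"`,
#'   `"transparent_perforated"` (the default, the full-modality divider used
#'   in the main learning protocol).
#' @param context_cues Logical; contextual wall cues on zones B and C.
#' @param sex `"female"`, `"male"`, or `"unspecified"`.
#' @param mode `"paired"` or `"solitary"`.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(divider = "transparent_perforated",
                           context_cues = FALSE,
                           sex = c("unspecified", "female", "male"),
                           mode = c("paired", "solitary")) {
  if (!(is.character(divider) && length(divider) == 1L &&
        divider %in% DIVIDER_TYPES))
    stop_validation("divider must be one of: ",
                    paste(DIVIDER_TYPES, collapse = ", "))
  sex <- match.arg(sex)
  mode <- match.arg(mode)
  if (!(is.logical(context_cues) && length(context_cues) == 1L &&
        !is.na(context_cues)))
    stop_validation("context_cues must be TRUE or FALSE")
  structure(list(divider = divider, context_cues = context_cues,
                 sex = sex, mode = mode),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("Condition: %s | divider %s | context cues %s | sex %s\n",
              x$mode, x$divider, if (x$context_cues) "on" else "off", x$sex))
  invisible(x)
}

condition_label <- function(cond) {
  paste(cond$mode, cond$divider,
        if (cond$context_cues) "ctx" else "noctx", cond$sex, sep = "/")
}

n_subjects_for_mode <- function(mode) if (mode == "paired") 2L else 1L

# validation errors carry their own condition class so the CLI can map them
# to exit code 2
stop_validation <- function(...) {
  msg <- paste0(...)
  stop(structure(class = c("coopmaze_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
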