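#' Scenario configuration
#'
#' A scenario bundles the four management-policy levers plus experiment
#' sizes. The Base Case is FIFO sequencing, no buffer hours, sequential
#' induction of anesthesia (no extra teams) and an open dedicated emergency
#' room.
#'
#' @param sequencing elective sequencing policy applied to each built room
#'   schedule: `"FIFO"` (leave the priority/FIFO order), `"SF"` (shortest
#'   expected slot first) or `"LF"` (longest first).
#' @param buffer_hours end-of-day buffer: rooms stay open this many hours
#'   past the 15:45 regular close (planning still books regular hours only).
#'   Capped so the effective close never passes 20:00.
#' @param parallel_induction logical; induce the next patient's anesthesia
#'   in a separate induction room while the previous case still occupies the
#'   OR. Schedules are then built on occupation (rather than presence)
#'   times.
#' @param extra_teams number of additional anesthesia teams (0-3) staffed
#'   for parallel inductions; requires `parallel_induction = TRUE` when
#'   positive. With 0 extra teams only the emergency-room team can be
#'   borrowed for overlap when that room is idle.
#' @param dedicated_emergency_or logical; keep the dedicated emergency room
#'   staffed and on stand-by. When `FALSE` the room is shut completely and
#'   emergencies go to the next available room.
#' @param replications,horizon_weeks,warmup_weeks experiment sizes: number
#'   of independent replications, post-warm-up weeks measured per
#'   replication, and warm-up weeks discarded while the waiting list reaches
#'   steady state.
#' @param base_seed seed of replication 1; replication `i` uses
#'   `base_seed + i - 1`, so scenarios run under common random numbers.
#' @param label short scenario name used in reports.
#' @return object of class `or_scenario`.
#' @examples
#' base_case()
#' scenario_config(sequencing = "SF", label = "shortest-first")
#' @export
scenario_config <- function(sequencing = c("FIFO", "SF", "LF"),
                            buffer_hours = 0,
                            parallel_induction = FALSE,
                            extra_teams = 0L,
                            dedicated_emergency_or = TRUE,
                            replications = 30L,
                            horizon_weeks = 52L,
                            warmup_weeks = 4L,
                            base_seed = 1L,
                            label = NULL) {
  sequencing <- match.arg(sequencing)
  if (!is.numeric(buffer_hours) || buffer_hours < 0 || buffer_hours > 4.25) {
    stop("`buffer_hours` must lie in [0, 4.25] (close capped at 20:00)")
  }
  extra_teams <- as.integer(extra_teams)
  if (extra_teams < 0L || extra_teams > 3L) {
    stop("`extra_teams` must be 0, 1, 2 or 3")
  }
  if (extra_teams > 0L && !parallel_induction) {
    stop("`extra_teams` > 0 requires `parallel_induction = TRUE`")
  }
  stopifnot(replications >= 1, horizon_weeks >= 1, warmup_weeks >= 0)
  if (is.null(label)) {
    label <- paste0(sequencing,
                    if (buffer_hours > 0) paste0("+buf", buffer_hours),
                    if (parallel_induction) paste0("+par", extra_teams),
                    if (!dedicated_emergency_or) "+noER")
    if (label == "FIFO") label <- "base"
  }
  structure(
    list(sequencing = sequencing,
         buffer_hours = buffer_hours,
         parallel_induction = isTRUE(parallel_induction),
         extra_teams = extra_teams,
         dedicated_emergency_or = isTRUE(dedicated_emergency_or),
         replications = as.integer(replications),
         horizon_weeks = as.integer(horizon_weeks),
         warmup_weeks = as.integer(warmup_weeks),
         base_seed = as.integer(base_seed),
         label = label),
    class = "or_scenario")
}

#' @rdname scenario_config
#' @param ... overrides passed to [scenario_config()].
#' @export
base_case <- function(...) scenario_config(...)

#' @export
print.or_scenario <- function(x, ...) {
  cat("Scenario '", x$label, "': ", x$sequencing,
      ", buffer ", x$buffer_hours, " h, parallel induction ",
      if (x$parallel_induction) paste0("on (+", x$extra_teams, " teams)")
      else "off",
      ", emergency OR ",
      if (x$dedicated_emergency_or) "open" else "closed", "\n", sep = "")
  cat("  ", x$replications, " replications x ", x$horizon_weeks,
      " weeks (+", x$warmup_weeks, " warm-up), base seed ",
      x$base_seed, "\n", sep = "")
  invisible(x)
}

effective_close <- function(scenario) {
  min(MIN_REG_CLOSE + 60 * scenario$buffer_hours, MIN_MAX_CLOSE)
}

#' Bundled preset experiments
#'
#' The four experiment families evaluated against the shared Base Case:
#' end-of-day buffer hours (1-4 h), parallel induction with 0-3 extra
#' anesthesia teams, SF/LF sequencing, and closing the dedicated emergency
#' room - 12 distinct scenarios in total.
#'
#' @param ... common overrides (e.g. `replications`, `horizon_weeks`,
#'   `base_seed`) applied to every preset.
#' @return named list of [scenario_config()] objects.
#' @export
preset_experiments <- function(...) {
  presets <- list(base = scenario_config(..., label = "base"))
  for (b in 1:4) {
    presets[[paste0("buffer", b)]] <-
      scenario_config(buffer_hours = b, ..., label = paste0("buffer", b, "h"))
  }
  for (k in 0:3) {
    presets[[paste0("parallel", k)]] <-
      scenario_config(parallel_induction = TRUE, extra_teams = k, ...,
                      label = paste0("parallel+", k))
  }
  presets$sf <- scenario_config(sequencing = "SF", ..., label = "SF")
  presets$lf <- scenario_config(sequencing = "LF", ..., label = "LF")
  presets$no_emergency_or <-
    scenario_config(dedicated_emergency_or = FALSE, ..., label = "no-ER")
  presets
}
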