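#' Planned slot length of a case
#'
#' The expected time a case blocks an operating room at planning time. In
#' the Base Case (sequential induction) this is the expected presence of
#' anesthesiologist (induction + occupation) plus expected cleaning; when
#' parallel induction is active, schedules are built on the expected
#' occupation plus cleaning only, which is what tightens the plan and lets
#' additional patients fit. Urgent patients are planned with their
#' specialty's medium-class means. Emergencies are never planned ahead;
#' their projected length (used when inserting them) is always
#' presence-based since their induction happens in-room.
#'
#' @param calib a [calibration()].
#' @param scenario a [scenario_config()].
#' @param specialty,acuity,class vectors describing the cases (recycled to a
#'   common length).
#' @return numeric vector of planned slot lengths in minutes.
#' @export
planned_slot_length <- function(calib, scenario, specialty, acuity,
                                class = "medium") {
  n <- max(length(specialty), length(acuity), length(class))
  specialty <- rep_len(specialty, n)
  acuity <- rep_len(acuity, n)
  class <- rep_len(class, n)
  dm <- calib$duration
  cls <- ifelse(acuity %in% c("semi_urgent", "very_urgent"), "medium", class)
  pres <- dm$presence_mean[cbind(specialty, cls)]
  pres <- ifelse(acuity == "emergency", pres * dm$emergency_mean_mult, pres)
  shrink <- scenario$parallel_induction & acuity != "emergency"
  pres * ifelse(shrink, 1 - dm$induction_fraction, 1) + dm$cleaning_mean
}

#' Re-sequence a built room schedule
#'
#' Applies a sequencing policy to one day's schedule of one room: the
#' patient set is unchanged, only the order (and hence the back-to-back
#' planned starts) changes. `"FIFO"` keeps the priority/FIFO order the
#' schedule was built in; `"SF"` sorts by ascending and `"LF"` by
#' descending planned slot length, ties broken by the original position.
#'
#' @param schedule data.frame with columns `pid` and `planned_len`, in
#'   built (priority-then-FIFO) order.
#' @param policy `"FIFO"`, `"SF"` or `"LF"`.
#' @return the schedule reordered, with `planned_start` recomputed
#'   back-to-back from the 08:30 opening.
#' @export
apply_sequencing <- function(schedule, policy = c("FIFO", "SF", "LF")) {
  policy <- match.arg(policy)
  n <- nrow(schedule)
  ord <- switch(policy,
                FIFO = seq_len(max(n, 0)),
                SF = order(schedule$planned_len, seq_len(n)),
                LF = order(-schedule$planned_len, seq_len(n)))
  out <- schedule[ord, , drop = FALSE]
  out$planned_start <- MIN_REG_OPEN +
    c(0, cumsum(out$planned_len))[seq_len(n)]
  rownames(out) <- NULL
  out
}

#' Build the preliminary day schedules of all departments
#'
#' Implements the departments' evening-before planning: for every room a
#' department holds on the given weekday, patients are appended from the
#' department's waiting list in priority order - semi-urgent patients first,
#' then previously deferred cases (in their original deferral order), then
#' electives FIFO - while the planned slot lengths fit inside the 435-minute
#' regular window. A patient that does not fit the currently least-loaded
#' room is skipped and remains on the list (smaller cases behind it may
#' still fit). Planning never books past the regular close: buffer hours are
#' execution-time capacity only. The sequencing policy is applied to each
#' finished room schedule.
#'
#' @param patients patient data.frame holding at least the listed ids.
#' @param wl waiting list: named list per department, each with integer id
#'   vectors `semi`, `deferred`, `elective`.
#' @param mss an MSS.
#' @param weekday 1-7; weekends (6, 7) build no schedules.
#' @param scenario a [scenario_config()].
#' @param calib a [calibration()].
#' @return list with `schedules` (named by room id: data.frames `pid`,
#'   `planned_start`, `planned_len`) and the consumed `wl`.
#' @export
build_day_schedules <- function(patients, wl, mss, weekday, scenario, calib) {
  schedules <- list()
  if (weekday > 5) return(list(schedules = schedules, wl = wl))
  day_mss <- mss[mss$weekday == weekday & mss$department %in% SPECIALTIES, ]
  for (dept in SPECIALTIES) {
    rooms <- day_mss$room_id[day_mss$department == dept]
    if (length(rooms) == 0) next
    q <- wl[[dept]]
    ids <- c(q$semi, q$deferred, q$elective)
    if (length(ids) == 0) {
      for (r in rooms) schedules[[r]] <-
          data.frame(pid = integer(0), planned_start = numeric(0),
                     planned_len = numeric(0))
      next
    }
    pr <- patients[ids, ]
    lens <- planned_slot_length(calib, scenario, pr$specialty, pr$acuity,
                                pr$class)
    loads <- setNames(numeric(length(rooms)), rooms)
    assign_room <- rep(NA_character_, length(ids))
    # smallest slot still ahead, for early termination of the scan
    min_ahead <- rev(cummin(rev(lens)))
    for (i in seq_along(ids)) {
      if (max(REGULAR_WINDOW_MIN - loads) < min_ahead[i]) break
      fits <- which(loads + lens[i] <= REGULAR_WINDOW_MIN)
      if (length(fits) == 0) next
      r <- fits[which.min(loads[fits])]
      loads[r] <- loads[r] + lens[i]
      assign_room[i] <- rooms[r]
    }
    for (r in rooms) {
      sel <- which(assign_room == r)
      sched <- data.frame(pid = ids[sel], planned_len = lens[sel])
      sched <- apply_sequencing(sched, scenario$sequencing)
      schedules[[r]] <- sched[, c("pid", "planned_start", "planned_len")]
    }
    taken <- ids[!is.na(assign_room)]
    wl[[dept]] <- list(semi = setdiff(q$semi, taken),
                       deferred = setdiff(q$deferred, taken),
                       elective = setdiff(q$elective, taken))
  }
  list(schedules = schedules, wl = wl)
}
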