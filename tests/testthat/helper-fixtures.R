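# Shared fixtures: deterministic calibrations, quiet arrival models, and a
# stripped-down MSS with a single elective room, used to make engine traces
# hand-checkable.

quiet_arrivals <- function() {
  arrival_model(
    urgent_day_rate = setNames(numeric(9), SPECIALTIES),
    urgent_night_rate_total = 0,
    emergency_day_rate = 0,
    emergency_night_rate = 0)
}

# all dispersions zero: every sampled duration equals its mean
det_duration_model <- function(...) {
  duration_model(cv = 0, cleaning_cv = 0,
                 car_mix = list(offset = 0, cv = 0, weight = 0.5), ...)
}

det_calibration <- function(weekly_volume = 100, ...) {
  calibration(arrival = quiet_arrivals(), duration = det_duration_model(),
              weekly_volume = weekly_volume, ...)
}

# 18-room MSS with one GVT room per weekday, the dedicated emergency room,
# and everything else closed
single_room_mss <- function(dept = "GVT") {
  rooms <- sprintf("R%02d", 1:18)
  grid <- expand.grid(weekday = 1:5, room_id = rooms,
                      stringsAsFactors = FALSE)
  grid$department <- "CLOSED"
  grid$department[grid$room_id == "R01"] <- dept
  grid$department[grid$room_id == "R18"] <- "EMERGENCY"
  attr(grid, "night_rooms") <- c("R16", "R17")
  validate_mss(grid)
}

# room metadata for direct exec_day toys: n open ordinary rooms of dept 0,
# optionally a dedicated emergency room appended
toy_meta <- function(n_rooms = 1, er = FALSE, dept = 0L) {
  n <- n_rooms + er
  list(open = rep(1L, n),
       dept = c(rep(as.integer(dept), n_rooms), if (er) -1L),
       is_er = c(rep(0L, n_rooms), if (er) 1L),
       is_night = rep(0L, n))
}

toy_sched <- function(room, planned_start, planned_len, induction,
                      occupation, cleaning, dept = 0L) {
  n <- length(room)
  list(pid = seq_len(n), room = as.integer(room),
       planned_start = planned_start, planned_len = planned_len,
       dept = rep(as.integer(dept), n),
       induction = induction, occupation = occupation, cleaning = cleaning)
}

no_breakins <- function() {
  list(pid = integer(0), ptype = integer(0), dept = integer(0),
       notice = numeric(0), ready = numeric(0), deadline = numeric(0),
       induction = numeric(0), occupation = numeric(0),
       cleaning = numeric(0), planned_len = numeric(0))
}

toy_breakin <- function(pid, type, notice, induction, occupation, cleaning,
                        planned_len, dept = 0L, ready = notice,
                        deadline = if (type == 2L) notice + 360 else 1e18) {
  list(pid = as.integer(pid), ptype = as.integer(type),
       dept = as.integer(dept), notice = notice, ready = ready,
       deadline = deadline, induction = induction, occupation = occupation,
       cleaning = cleaning, planned_len = planned_len)
}

run_toy_day <- function(meta, sched, breaks = no_breakins(),
                        scenario = scenario_config(), avail = NULL,
                        weekend = FALSE) {
  if (is.null(avail)) avail <- numeric(length(meta$open))
  orsim:::exec_day(meta, avail, sched, breaks, scenario, weekend = weekend)
}
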