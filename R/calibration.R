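#' Calibration: arrival model, duration model and volume target
#'
#' Bundles everything the synthetic input model needs. The weekly volume
#' target is the expected total surgical demand (electives + urgents +
#' emergencies); under the default arrival rates the implied elective demand
#' is `345 - 5*12.6 - 7*0.48 - 7*(2.8+0.8) = 253.44` electives per week,
#' i.e. about 72-73% of all generated patients.
#'
#' Department-level elective demand is split proportionally to each
#' department's bookable capacity under the given MSS (room-days times 435
#' regular minutes divided by the department's expected slot length), so
#' every department's schedule fills at a comparable rate.
#'
#' @param arrival an [arrival_model()].
#' @param duration a [duration_model()].
#' @param weekly_volume expected total surgeries per week, all acuities.
#' @param notice_lead minutes between the theatre coordinator learning of an
#'   incoming urgent/emergency case and the patient being ready for surgery;
#'   room selection happens at notice, waiting time is measured from ready.
#'   The default of 0 treats the advance notice as a real-world mitigation
#'   outside the model (waiting is then simply arrival to room entry).
#' @return object of class `or_calibration`.
#' @export
calibration <- function(arrival = arrival_model(),
                        duration = duration_model(),
                        weekly_volume = 345,
                        notice_lead = 0) {
  stopifnot(inherits(arrival, "or_arrival_model"),
            inherits(duration, "or_duration_model"),
            weekly_volume >= 0, notice_lead >= 0)
  structure(list(arrival = arrival, duration = duration,
                 weekly_volume = weekly_volume, notice_lead = notice_lead),
            class = "or_calibration")
}

#' @rdname calibration
#' @export
default_calibration <- function() calibration()

#' @export
print.or_calibration <- function(x, ...) {
  cat("Operating theatre calibration\n")
  cat("  weekly volume target:", x$weekly_volume, "surgeries\n")
  cat("  expected urgents/week:", round(expected_urgents_week(x$arrival), 2),
      "| emergencies/week:", round(expected_emergencies_week(x$arrival), 2), "\n")
  cat("  implied electives/week:", round(elective_weekly_target(x), 2), "\n")
  invisible(x)
}

expected_urgents_week <- function(arrival) {
  5 * sum(arrival$urgent_day_rate) + 7 * arrival$urgent_night_rate_total
}

expected_emergencies_week <- function(arrival) {
  7 * (arrival$emergency_day_rate + arrival$emergency_night_rate)
}

# expected weekly elective demand implied by the volume target
elective_weekly_target <- function(calib) {
  max(0, calib$weekly_volume -
        expected_urgents_week(calib$arrival) -
        expected_emergencies_week(calib$arrival))
}

# expected planned slot length per department for an elective of average
# class mix (used only to apportion demand across departments)
dept_mean_slot <- function(duration) {
  w <- duration$class_mix
  pres <- as.vector(duration$presence_mean %*% w)
  setNames(pres + duration$cleaning_mean, SPECIALTIES)
}

# department weekly elective arrival rates, proportional to bookable capacity
dept_elective_rates <- function(calib, mss) {
  total <- elective_weekly_target(calib)
  rd <- mss_roomdays(mss)
  cap <- rd * REGULAR_WINDOW_MIN / dept_mean_slot(calib$duration)
  if (sum(cap) == 0) return(setNames(numeric(9), SPECIALTIES))
  total * cap / sum(cap)
}

# department weights for assigning a specialty to emergency patients
dept_emergency_weights <- function(calib, mss) {
  r <- dept_elective_rates(calib, mss) + 5 * calib$arrival$urgent_day_rate
  if (sum(r) == 0) r[] <- 1
  r / sum(r)
}
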