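#' Patient records
#'
#' Patients are rows of a plain data.frame with columns `id`, `specialty`,
#' `acuity`, `class`, `arrival` (absolute minutes since simulation start),
#' `induction`, `occupation`, `cleaning` (sampled realized durations,
#' minutes) and `deferrals` (times the case has been pushed to a later day).
#' Elective patients come from the waiting-list pool and always arrive
#' before their scheduled day; urgent and emergency patients arrive
#' continuously and disrupt the plan.
#'
#' @name patient-records
NULL

# build a patient frame, sampling durations group-wise for speed
make_patients <- function(calib, specialty, acuity, class, arrival,
                          start_id = 1L) {
  n <- length(specialty)
  if (n == 0) {
    return(data.frame(id = integer(0), specialty = character(0),
                      acuity = character(0), class = character(0),
                      arrival = numeric(0), induction = numeric(0),
                      occupation = numeric(0), cleaning = numeric(0),
                      deferrals = integer(0)))
  }
  induction <- occupation <- cleaning <- numeric(n)
  key <- paste(specialty, acuity, class, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    d <- sample_case_durations(calib$duration, parts[1], parts[2], parts[3],
                               n = length(idx))
    induction[idx] <- d$induction
    occupation[idx] <- d$occupation
    cleaning[idx] <- d$cleaning
  }
  data.frame(id = seq.int(start_id, length.out = n),
             specialty = specialty, acuity = acuity, class = class,
             arrival = arrival, induction = induction,
             occupation = occupation, cleaning = cleaning,
             deferrals = 0L)
}

draw_classes <- function(calib, n) {
  if (n == 0) return(character(0))
  sample(DURATION_CLASSES, n, replace = TRUE, prob = calib$duration$class_mix)
}

#' Generate the elective demand of one week
#'
#' Draws the elective patients entering the waiting-list pool during one
#' week. Department weekly rates are derived from the calibration volume
#' target and the MSS (see [calibration()]); arrivals are Poisson per
#' weekday and uniformly timed during office hours (07:00-16:00), so each
#' patient is on the list no later than the evening before the earliest day
#' it could be scheduled. Duration classes are drawn from the calibrated
#' class mix; all durations are sampled at generation time.
#'
#' @param calib an [calibration()].
#' @param mss an MSS ([default_mss()]).
#' @param week_start_day 0-based simulation day index of the week's Monday.
#' @param start_id first patient id to use.
#' @return patient data.frame (see [patient-records]).
#' @export
generate_weekly_elective_pool <- function(calib, mss, week_start_day = 0L,
                                          start_id = 1L) {
  rates <- dept_elective_rates(calib, mss)
  daily <- rep(rates / 5, each = 5)           # dept x weekday
  counts <- rpois(length(daily), daily)
  dept <- rep(rep(SPECIALTIES, each = 5), counts)
  day <- rep(rep(0:4, times = 9), counts) + week_start_day
  n <- length(dept)
  arrival <- day * MIN_PER_DAY + runif(n, 420, 960)
  ord <- order(arrival)
  make_patients(calib, dept[ord], rep("elective", n),
                draw_classes(calib, n), arrival[ord], start_id = start_id)
}

#' Generate urgent and emergency arrivals for one calendar day
#'
#' Draws the unplanned demand whose arrival (notice) time falls on the given
#' day: urgent daytime arrivals per specialty (weekdays only), emergencies
#' during the day, and the night streams of the night window starting at
#' 22:00 that day (arrivals after midnight are returned with times past
#' 1440 and belong to the next calendar day).
#'
#' @inheritParams generate_weekly_elective_pool
#' @param day 0-based simulation day index.
#' @param weekday integer 1-7 (1 = Monday); urgent daytime rates apply to
#'   weekdays 1-5 only.
#' @return patient data.frame; urgent patients are already split into
#'   semi-urgent and very-urgent.
#' @export
generate_day_arrivals <- function(calib, mss, day, weekday, start_id = 1L) {
  arr <- calib$arrival
  spec <- character(0); acu <- character(0); when <- numeric(0)

  day_counts <- sample_arrival_counts(arr, "day", weekday = weekday <= 5)
  nu <- day_counts$urgent[1, ]
  if (sum(nu) > 0) {
    s <- rep(SPECIALTIES, nu)
    t <- sample_arrival_times(sum(nu), "day")
    spec <- c(spec, s); when <- c(when, t)
    acu <- c(acu, assign_urgency_split(sum(nu), arr))
  }
  night_counts <- sample_arrival_counts(arr, "night", weekday = weekday <= 5)
  nn <- night_counts$urgent[1, ]
  if (sum(nn) > 0) {
    s <- rep(SPECIALTIES, nn)
    t <- sample_arrival_times(sum(nn), "night")
    spec <- c(spec, s); when <- c(when, t)
    acu <- c(acu, assign_urgency_split(sum(nn), arr))
  }
  n_em <- day_counts$emergency + night_counts$emergency
  if (n_em > 0) {
    wts <- dept_emergency_weights(calib, mss)
    s <- sample(SPECIALTIES, n_em, replace = TRUE, prob = wts)
    t <- c(sample_arrival_times(day_counts$emergency, "day"),
           sample_arrival_times(night_counts$emergency, "night"))
    spec <- c(spec, s); when <- c(when, t)
    acu <- c(acu, rep("emergency", n_em))
  }
  n <- length(spec)
  if (n == 0) return(make_patients(calib, character(0), character(0),
                                   character(0), numeric(0)))
  cls <- ifelse(acu == "emergency", draw_classes(calib, n), "medium")
  ord <- order(when)
  make_patients(calib, spec[ord], acu[ord], cls[ord],
                day * MIN_PER_DAY + when[ord], start_id = start_id)
}
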