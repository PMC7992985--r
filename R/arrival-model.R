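#' Arrival model for urgent and emergency patients
#'
#' Defines the stochastic arrival processes of unplanned surgical demand.
#' Urgent patients (semi-urgent and very-urgent) arrive per specialty with
#' department-specific daytime rates on weekdays; at night only a small total
#' urgent stream remains. Emergencies arrive independently of specialty with
#' distinct day and night rates every day of the week. Counts per window are
#' Poisson by default; a negative-binomial option matches the slight
#' overdispersion of the observed emergency counts.
#'
#' Default rates (patients per window): per-specialty urgent daytime rates
#' summing to 12.6 per weekday, 0.48 urgent patients per night, 2.8
#' emergencies per daytime window (06:00-22:00) and 0.8 per night
#' (22:00-06:00). About half of all urgent patients are very-urgent.
#'
#' @param urgent_day_rate named numeric vector, mean urgent arrivals per
#'   specialty in the 06:00-22:00 window of a weekday. Names must be the nine
#'   codes in [SPECIALTIES].
#' @param urgent_night_rate_total mean urgent arrivals per night (22:00-06:00),
#'   all specialties combined; split across specialties proportionally to
#'   their daytime rates.
#' @param emergency_day_rate,emergency_night_rate mean emergency arrivals per
#'   daytime window / per night.
#' @param very_urgent_fraction probability that an urgent patient is
#'   very-urgent (needs surgery within 6 h) rather than semi-urgent (24 h).
#' @param family counting distribution for window counts: `"poisson"`
#'   (default) or `"nbinom"`.
#' @param emergency_day_sd,emergency_night_sd standard deviations used to set
#'   the negative-binomial size when `family = "nbinom"`; ignored otherwise.
#' @return an object of class `or_arrival_model`.
#' @examples
#' m <- arrival_model()
#' sum(m$urgent_day_rate)  # 12.6 urgent patients per weekday
#' @export
arrival_model <- function(urgent_day_rate = c(
                            GVT = 2.4, VS = 1.3, GYN = 0.6, CAR = 1.8,
                            PED = 1.0, OMS = 0.2, NS = 0.5, TS = 4.7,
                            URO = 0.1),
                          urgent_night_rate_total = 0.48,
                          emergency_day_rate = 2.8,
                          emergency_night_rate = 0.8,
                          very_urgent_fraction = 0.5,
                          family = c("poisson", "nbinom"),
                          emergency_day_sd = 1.9,
                          emergency_night_sd = 1.1) {
  family <- match.arg(family)
  if (is.null(names(urgent_day_rate)) ||
      !setequal(names(urgent_day_rate), SPECIALTIES)) {
    stop("`urgent_day_rate` must be named with the nine specialty codes")
  }
  urgent_day_rate <- urgent_day_rate[SPECIALTIES]
  rates <- c(urgent_day_rate, urgent_night_rate_total,
             emergency_day_rate, emergency_night_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("arrival rates must be finite and non-negative")
  }
  if (very_urgent_fraction < 0 || very_urgent_fraction > 1) {
    stop("`very_urgent_fraction` must lie in [0, 1]")
  }
  structure(
    list(urgent_day_rate = urgent_day_rate,
         urgent_night_rate_total = urgent_night_rate_total,
         urgent_night_rate = if (sum(urgent_day_rate) > 0) {
           urgent_night_rate_total * urgent_day_rate / sum(urgent_day_rate)
         } else {
           setNames(rep(urgent_night_rate_total / 9, 9), SPECIALTIES)
         },
         emergency_day_rate = emergency_day_rate,
         emergency_night_rate = emergency_night_rate,
         very_urgent_fraction = very_urgent_fraction,
         family = family,
         emergency_day_sd = emergency_day_sd,
         emergency_night_sd = emergency_night_sd),
    class = "or_arrival_model")
}

#' @export
print.or_arrival_model <- function(x, ...) {
  cat("Arrival model (", x$family, " counts)\n", sep = "")
  cat("  urgent, daytime weekday: total",
      round(sum(x$urgent_day_rate), 2), "per day\n")
  cat("  urgent, night: total", x$urgent_night_rate_total, "per night\n")
  cat("  emergencies:", x$emergency_day_rate, "per day /",
      x$emergency_night_rate, "per night\n")
  cat("  very-urgent fraction of urgents:", x$very_urgent_fraction, "\n")
  invisible(x)
}

# draw one count for a given mean (and sd when negative binomial)
draw_count <- function(n, mean, sd, family) {
  if (mean == 0) return(integer(n))
  if (family == "nbinom" && !is.null(sd) && is.finite(sd) && sd^2 > mean) {
    size <- mean^2 / (sd^2 - mean)
    return(rnbinom(n, size = size, mu = mean))
  }
  rpois(n, mean)
}

#' Sample arrival counts for one window
#'
#' Draws the number of urgent arrivals per specialty and the number of
#' emergency arrivals for a single day/night window. Urgent daytime arrivals
#' occur on weekdays only; emergencies and the small urgent night stream run
#' every day of the week.
#'
#' @param model an [arrival_model()].
#' @param window `"day"` (06:00-22:00) or `"night"` (22:00-06:00).
#' @param weekday logical, is this a Monday-Friday window? Urgent daytime
#'   rates are defined per weekday and are zero on weekends.
#' @param n number of independent windows to draw.
#' @return list with `urgent` (an `n` x 9 integer matrix, one column per
#'   specialty) and `emergency` (integer vector of length `n`).
#' @export
sample_arrival_counts <- function(model, window = c("day", "night"),
                                  weekday = TRUE, n = 1L) {
  stopifnot(inherits(model, "or_arrival_model"), n >= 0)
  window <- match.arg(window)
  urg_rates <- if (window == "day") {
    if (weekday) model$urgent_day_rate else setNames(numeric(9), SPECIALTIES)
  } else {
    model$urgent_night_rate
  }
  urgent <- vapply(urg_rates, function(r) draw_count(n, r, NULL, model$family),
                   integer(n))
  if (n == 1L) urgent <- matrix(urgent, nrow = 1, dimnames = list(NULL, SPECIALTIES))
  em_rate <- if (window == "day") model$emergency_day_rate else model$emergency_night_rate
  em_sd <- if (window == "day") model$emergency_day_sd else model$emergency_night_sd
  emergency <- draw_count(n, em_rate, em_sd, model$family)
  list(urgent = urgent, emergency = emergency)
}

#' Sample arrival times within a window
#'
#' Places `count` arrivals uniformly at random inside the requested window
#' and returns them sorted. Times are minutes of day; night times run from
#' 1320 (22:00) to 1800 (06:00 next day), i.e. values of 1440 and above fall
#' in the following calendar day.
#'
#' @param count non-negative integer.
#' @param window `"day"` or `"night"`.
#' @return sorted numeric vector of length `count`.
#' @export
sample_arrival_times <- function(count, window = c("day", "night")) {
  window <- match.arg(window)
  stopifnot(length(count) == 1L, count >= 0)
  if (count == 0) return(numeric(0))
  lim <- if (window == "day") c(MIN_DAY_START, MIN_DAY_END)
         else c(MIN_DAY_END, MIN_DAY_START + MIN_PER_DAY)
  sort(runif(count, lim[1], lim[2]))
}

#' Split urgent patients into semi-urgent and very-urgent
#'
#' Each generic-urgent patient is independently very-urgent with probability
#' `model$very_urgent_fraction` (default 0.5: about half of the urgent
#' patients require surgery within 6 h, the others within 24 h).
#'
#' @param n number of urgent patients.
#' @param model an [arrival_model()].
#' @return character vector of `"very_urgent"` / `"semi_urgent"`.
#' @export
assign_urgency_split <- function(n, model) {
  stopifnot(inherits(model, "or_arrival_model"), n >= 0)
  ifelse(runif(n) < model$very_urgent_fraction, "very_urgent", "semi_urgent")
}
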