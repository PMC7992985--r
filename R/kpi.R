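#' Performance indicators of one replication
#'
#' Computes the standard operating-theatre indicators from a replication
#' log:
#' \describe{
#'   \item{treated/deferred per week}{counts of performed surgeries and of
#'     interday deferral events, per 7-day week.}
#'   \item{waiting times}{intraday delay per acuity: for scheduled patients
#'     the gap between the (frozen) planned start and actual room entry;
#'     for urgent/emergency break-ins the gap between ready-for-surgery
#'     (arrival plus the notice lead) and room entry. A deferred patient
#'     incurs no waiting on the deferral day - the reference resets to the
#'     updated planned start on the day of surgery.}
#'   \item{utilization}{room utilization counts surgery + cleaning time,
#'     system utilization additionally anesthesia (induction) time; both are
#'     reported for the regular (08:30-15:45) and extended (15:45-20:00)
#'     windows over all staffed elective room-days (the dedicated emergency
#'     room is excluded and reported via its own break-in statistics).}
#'   \item{overtime/undertime}{minutes the last activity of an elective
#'     room-day runs past / falls short of the regular close; a room-day has
#'     overtime or undertime, never both.}
#'   \item{anesthesia turnover}{mean gap between a patient's room exit and
#'     the next patient's procedure start over consecutive same-room pairs.}
#' }
#'
#' @param rep an [or_replication][run_replication()].
#' @return one-row data.frame of indicators.
#' @export
compute_kpis <- function(rep) {
  cases <- rep$cases
  weeks <- rep$horizon_weeks
  tr <- cases[cases$treated, , drop = FALSE]
  if (nrow(cases) == 0) {
    warning("empty case log; returning zero indicators")
  }

  wait_by <- function(acu) {
    w <- tr$waiting[tr$acuity == acu]
    if (length(w) == 0) NA_real_ else mean(w)
  }

  ou <- over_undertime(rep)
  ut_rr <- utilization(rep, "room", "regular")
  ut_re <- utilization(rep, "room", "extended")
  ut_sr <- utilization(rep, "system", "regular")
  ut_se <- utilization(rep, "system", "extended")

  data.frame(
    treated_per_week = nrow(tr) / weeks,
    deferrals_per_week = sum(!cases$treated) / weeks,
    waiting_elective = wait_by("elective"),
    waiting_semi_urgent = wait_by("semi_urgent"),
    waiting_very_urgent = wait_by("very_urgent"),
    waiting_emergency = wait_by("emergency"),
    room_util_regular = ut_rr,
    room_util_extended = ut_re,
    system_util_regular = ut_sr,
    system_util_extended = ut_se,
    overtime_per_room_day = mean(ou$overtime),
    undertime_per_room_day = mean(ou$undertime),
    anesthesia_turnover = anesthesia_turnover(rep))
}

# day-program end of each elective room-day: last cleaning end over cases
# that entered the room before 22:00 (night-room around-the-clock service is
# not staff overtime)
room_day_last_end <- function(rep) {
  rooms <- rep$rooms
  el <- rooms[rooms$elective_room, , drop = FALSE]
  if (nrow(el) == 0) {
    return(data.frame(day = integer(0), room = integer(0),
                      last_end = numeric(0)))
  }
  tr <- rep$cases[rep$cases$treated &
                    rep$cases$room_enter < MIN_DAY_END, , drop = FALSE]
  key_el <- paste(el$day, el$room)
  key_tr <- paste(tr$day, tr$room)
  last <- tapply(tr$clean_end, key_tr, max)
  le <- as.numeric(last[key_el])
  le[is.na(le)] <- 0
  data.frame(day = el$day, room = el$room, last_end = le)
}

#' Overtime and undertime per elective room-day
#'
#' @inheritParams compute_kpis
#' @return data.frame with one row per staffed elective room-day and
#'   columns `overtime`, `undertime` (minutes; an empty room-day has the
#'   full 435-minute regular window as undertime).
#' @export
over_undertime <- function(rep) {
  le <- room_day_last_end(rep)
  end_ <- pmax(le$last_end, MIN_REG_OPEN)
  data.frame(day = le$day, room = le$room,
             overtime = pmax(0, end_ - MIN_REG_CLOSE),
             undertime = pmax(0, MIN_REG_CLOSE - end_))
}

clip_len <- function(a, b, lo, hi) pmax(0, pmin(b, hi) - pmax(a, lo))

#' Utilization of the elective operating rooms
#'
#' @inheritParams compute_kpis
#' @param mode `"room"` (surgery + cleaning) or `"system"` (anesthesia +
#'   surgery + cleaning).
#' @param window `"regular"` (08:30-15:45) or `"extended"` (15:45-20:00).
#' @return overall busy fraction across all staffed elective room-days.
#' @export
utilization <- function(rep, mode = c("room", "system"),
                        window = c("regular", "extended")) {
  mode <- match.arg(mode)
  window <- match.arg(window)
  rooms <- rep$rooms
  n_rd <- sum(rooms$elective_room)
  if (n_rd == 0) return(NA_real_)
  lim <- if (window == "regular") c(MIN_REG_OPEN, MIN_REG_CLOSE)
         else c(MIN_REG_CLOSE, MIN_MAX_CLOSE)
  el_key <- paste(rooms$day[rooms$elective_room], rooms$room[rooms$elective_room])
  tr <- rep$cases[rep$cases$treated, , drop = FALSE]
  tr <- tr[paste(tr$day, tr$room) %in% el_key, , drop = FALSE]
  busy <- sum(clip_len(tr$proc_start, tr$clean_end, lim[1], lim[2]))
  if (mode == "system") {
    # induction runs [ind_start, ind_start + duration], in-room or in a
    # separate induction room; either way it is system time of this case
    ind_end <- tr$ind_start + tr$induction_dur
    busy <- busy + sum(clip_len(tr$ind_start, ind_end, lim[1], lim[2]))
  }
  busy / (n_rd * (lim[2] - lim[1]))
}

#' Mean anesthesia turnover time
#'
#' Gap between a patient's room exit and the next patient's procedure start,
#' averaged over consecutive treated pairs within each elective room-day.
#'
#' @inheritParams compute_kpis
#' @return minutes, or `NA` when no room-day has two cases.
#' @export
anesthesia_turnover <- function(rep) {
  tr <- rep$cases[rep$cases$treated, , drop = FALSE]
  rooms <- rep$rooms
  el_key <- paste(rooms$day[rooms$elective_room], rooms$room[rooms$elective_room])
  tr <- tr[paste(tr$day, tr$room) %in% el_key, , drop = FALSE]
  if (nrow(tr) < 2) return(NA_real_)
  tr <- tr[order(tr$day, tr$room, tr$room_enter), ]
  same <- tr$day[-1] == tr$day[-nrow(tr)] & tr$room[-1] == tr$room[-nrow(tr)]
  gaps <- (tr$proc_start[-1] - tr$room_exit[-nrow(tr)])[same]
  if (length(gaps) == 0) NA_real_ else mean(gaps)
}

#' Aggregate replication indicators into 95% confidence intervals
#'
#' Means and two-sided 95% t-intervals across independent replications, one
#' row per indicator. With a single replication the interval is undefined
#' and flagged.
#'
#' @param kpis data.frame of per-replication indicator rows
#'   ([compute_kpis()]), one row per replication.
#' @return data.frame with columns `kpi`, `mean`, `half_width`, `lower`,
#'   `upper`, `n`.
#' @export
aggregate_replications <- function(kpis) {
  num <- kpis[vapply(kpis, is.numeric, logical(1))]
  num <- num[, !(names(num) %in% c("rep", "seed")), drop = FALSE]
  n <- nrow(num)
  if (n < 1) stop("need at least one replication")
  res <- lapply(names(num), function(k) {
    x <- num[[k]][!is.na(num[[k]])]
    m <- if (length(x)) mean(x) else NA_real_
    hw <- if (length(x) >= 2) qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
          else NA_real_
    data.frame(kpi = k, mean = m, half_width = hw,
               lower = m - hw, upper = m + hw, n = length(x))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("or_ci_report", class(out))
  out
}

#' Do two confidence intervals overlap?
#'
#' The scenario-comparison convention: when the 95% intervals of two
#' scenarios do not overlap, their difference is statistically significant
#' at the 0.05 level.
#'
#' @param a,b rows (or lists) with `lower` and `upper`.
#' @return logical.
#' @export
ci_overlap <- function(a, b) {
  !(a$upper < b$lower || b$upper < a$lower)
}

#' Paired-contrast confidence interval
#'
#' 95% t-interval of the per-replication difference `a - b` between two
#' scenarios run under common random numbers; the pairing removes the shared
#' demand noise and sharpens policy contrasts.
#'
#' @param a,b numeric vectors of a per-replication indicator, same length
#'   and seed order.
#' @return list with `mean`, `lower`, `upper`.
#' @export
contrast_ci <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  m <- mean(d)
  hw <- qt(0.975, length(d) - 1) * sd(d) / sqrt(length(d))
  list(mean = m, lower = m - hw, upper = m + hw)
}
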