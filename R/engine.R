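# Replication driver: generates demand, freezes schedules the evening
# before, hands each day to the compiled discrete-event executor, and keeps
# the waiting-list state (semi-urgent, deferred, elective tiers) across days.

ACUITY_INT <- c(elective = 0L, semi_urgent = 1L, very_urgent = 2L,
                emergency = 3L)

# growable column store for patients (fast append, O(1) lookup by id)
new_patient_store <- function(cap = 4096L) {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- cap
  for (col in c("arrival", "induction", "occupation", "cleaning")) {
    e[[col]] <- numeric(cap)
  }
  for (col in c("spec_i", "acu_i", "cls_i", "deferrals")) {
    e[[col]] <- integer(cap)
  }
  e
}

store_add <- function(st, df) {
  n_new <- nrow(df)
  if (n_new == 0) return(integer(0))
  while (st$n + n_new > st$cap) {
    st$cap <- st$cap * 2L
    for (col in c("arrival", "induction", "occupation", "cleaning",
                  "spec_i", "acu_i", "cls_i", "deferrals")) {
      length(st[[col]]) <- st$cap
    }
  }
  idx <- st$n + seq_len(n_new)
  st$arrival[idx] <- df$arrival
  st$induction[idx] <- df$induction
  st$occupation[idx] <- df$occupation
  st$cleaning[idx] <- df$cleaning
  st$spec_i[idx] <- match(df$specialty, SPECIALTIES)
  st$acu_i[idx] <- ACUITY_INT[df$acuity]
  st$cls_i[idx] <- match(df$class, DURATION_CLASSES)
  st$deferrals[idx] <- 0L
  st$n <- st$n + n_new
  idx
}

# lightweight data.frame view for the scheduler
store_view <- function(st) {
  n <- st$n
  data.frame(specialty = SPECIALTIES[st$spec_i[seq_len(n)]],
             acuity = names(ACUITY_INT)[st$acu_i[seq_len(n)] + 1L],
             class = DURATION_CLASSES[st$cls_i[seq_len(n)]])
}

empty_wl <- function() {
  setNames(lapply(SPECIALTIES, function(s)
    list(semi = integer(0), deferred = integer(0), elective = integer(0))),
    SPECIALTIES)
}

# per-weekday room metadata in executor layout (0-based departments)
room_meta <- function(mss, scenario) {
  rooms <- sort(unique(mss$room_id))
  er <- attr(mss, "emergency_room")
  night <- attr(mss, "night_rooms")
  metas <- vector("list", 7)
  for (wd in 1:7) {
    if (wd <= 5) {
      day <- mss[mss$weekday == wd, ]
      dept <- day$department[match(rooms, day$room_id)]
    } else {
      dept <- rep("CLOSED", length(rooms))
    }
    is_er <- rooms == er
    is_night <- rooms %in% night
    open <- (dept %in% SPECIALTIES & !is_er) |
      (is_er & scenario$dedicated_emergency_or) | is_night
    dept_i <- ifelse(dept %in% SPECIALTIES, match(dept, SPECIALTIES) - 1L, -1L)
    metas[[wd]] <- list(room_id = rooms,
                        open = as.integer(open),
                        dept = as.integer(dept_i),
                        is_er = as.integer(is_er),
                        is_night = as.integer(is_night))
  }
  metas
}

# projected room-blocking length of a break-in (in-room induction, so always
# presence-based regardless of the induction mode)
breakin_plen <- function(calib, spec_i, acu_i, cls_i) {
  dm <- calib$duration
  cls <- ifelse(acu_i == 2L, 2L, cls_i)   # very-urgent: medium
  pres <- dm$presence_mean[cbind(spec_i, cls)]
  pres <- ifelse(acu_i == 3L, pres * dm$emergency_mean_mult, pres)
  pres + dm$cleaning_mean
}

# execute one day through the compiled core; sched/breaks are lists of
# parallel vectors (see run_replication); times are minutes of this day
exec_day <- function(meta, avail_from, sched, breaks, scenario,
                     weekend = FALSE) {
  n_s <- length(sched$pid)
  n_b <- length(breaks$pid)
  pat <- list(
    ptype = c(rep(0L, n_s), breaks$ptype),
    dept = c(sched$dept, breaks$dept),
    sched_room = c(sched$room, rep(-1L, n_b)),
    notice = c(rep(-1, n_s), breaks$notice),
    ready = c(rep(0, n_s), breaks$ready),
    deadline = c(rep(1e18, n_s), breaks$deadline),
    induction = c(sched$induction, breaks$induction),
    occupation = c(sched$occupation, breaks$occupation),
    cleaning = c(sched$cleaning, breaks$cleaning),
    planned_len = c(sched$planned_len, breaks$planned_len))
  rooms <- list(open = meta$open, is_er = meta$is_er,
                is_night = meta$is_night, dept = meta$dept,
                avail_from = avail_from)
  params <- list(reg_open = MIN_REG_OPEN, reg_close = MIN_REG_CLOSE,
                 eff_close = effective_close(scenario),
                 night_open = MIN_DAY_END, night_end = MIN_DAY_START,
                 parallel = as.integer(scenario$parallel_induction),
                 weekend = as.integer(weekend),
                 extra_teams = scenario$extra_teams,
                 max_ind_rooms = 13L)
  .exec_day_cpp(rooms, pat, params)
}

#' Run one simulation replication
#'
#' Simulates the full theatre for `warmup_weeks + horizon_weeks` weeks under
#' one scenario and one seed. Each day: elective demand joins the
#' departments' waiting lists; urgent and emergency arrivals are drawn; the
#' frozen day schedules are executed by the discrete-event core (break-ins,
#' buffer rules, deferrals); deferred cases re-enter the next day's program
#' ahead of newly booked electives; and the next day's schedules are frozen
#' in the evening. Identical `(scenario, seed)` pairs yield identical
#' results.
#'
#' @param scenario a [scenario_config()].
#' @param calib a [calibration()].
#' @param mss an MSS ([default_mss()]).
#' @param horizon_weeks,warmup_weeks weeks measured / discarded (defaults
#'   from the scenario).
#' @param seed RNG seed for this replication.
#' @return object of class `or_replication`: list with `cases` (one row per
#'   patient-day: realized sub-process timestamps in minutes of day,
#'   disposition `"treated"`/`"deferred"`, waiting time), `rooms` (one row
#'   per staffed room-day with the end of its last activity), and the run
#'   dimensions. Only post-warm-up days are logged.
#' @export
run_replication <- function(scenario, calib = default_calibration(),
                            mss = default_mss(),
                            horizon_weeks = scenario$horizon_weeks,
                            warmup_weeks = scenario$warmup_weeks,
                            seed = scenario$base_seed) {
  set.seed(seed)
  metas <- room_meta(mss, scenario)
  rooms <- metas[[1]]$room_id
  n_rooms <- length(rooms)
  st <- new_patient_store()
  wl <- empty_wl()
  frozen <- list()
  avail <- numeric(n_rooms)
  carry_break <- integer(0)   # break-ins past midnight
  carry_semi <- integer(0)    # semi-urgents arriving past midnight
  elec_pending <- list(id = integer(0), jday = integer(0))
  total_days <- 7L * (warmup_weeks + horizon_weeks)
  warm_days <- 7L * warmup_weeks
  acc <- list()
  room_acc <- list()
  lead <- calib$notice_lead %||% 30

  for (d in seq_len(total_days)) {
    wd <- ((d - 1L) %% 7L) + 1L
    meta <- metas[[wd]]

    if (wd == 1L) {
      pool <- generate_weekly_elective_pool(calib, mss, week_start_day = d - 1L,
                                            start_id = st$n + 1L)
      ids <- store_add(st, pool)
      if (length(ids)) {
        # electives join the list on their arrival day (before that
        # evening's freeze), never earlier
        elec_pending$id <- c(elec_pending$id, ids)
        elec_pending$jday <- c(elec_pending$jday,
                               floor(pool$arrival / MIN_PER_DAY) + 1L)
      }
    }
    if (length(elec_pending$id)) {
      due <- elec_pending$jday <= d
      for (i in elec_pending$id[due]) {
        s <- SPECIALTIES[st$spec_i[i]]
        wl[[s]]$elective <- c(wl[[s]]$elective, i)
      }
      elec_pending$id <- elec_pending$id[!due]
      elec_pending$jday <- elec_pending$jday[!due]
    }

    arr <- generate_day_arrivals(calib, mss, day = d - 1L, weekday = wd,
                                 start_id = st$n + 1L)
    ids <- store_add(st, arr)
    today_break <- carry_break
    carry_break <- integer(0)
    new_semi <- carry_semi
    carry_semi <- integer(0)
    if (length(ids)) {
      same_day <- floor(arr$arrival / MIN_PER_DAY) == (d - 1L)
      is_semi <- arr$acuity == "semi_urgent"
      new_semi <- c(new_semi, ids[is_semi & same_day])
      carry_semi <- ids[is_semi & !same_day]
      brk <- ids[!is_semi]
      brk_same <- same_day[!is_semi]
      today_break <- c(today_break, brk[brk_same])
      carry_break <- brk[!brk_same]
    }
    for (i in new_semi) {
      s <- SPECIALTIES[st$spec_i[i]]
      wl[[s]]$semi <- c(wl[[s]]$semi, i)
    }

    # ---- execute today ----
    sp <- flatten_schedules(frozen, rooms, st)
    bp <- breakin_inputs(calib, st, today_break, d, lead)
    res <- exec_day(meta, avail, sp, bp, scenario, weekend = wd > 5L)
    avail <- pmax(0, res$room_last_end - MIN_PER_DAY)

    n_s <- length(sp$pid)
    all_pid <- c(sp$pid, bp$pid)
    dispo <- res$disposition

    # deferred scheduled cases re-enter their department's program
    def_idx <- which(dispo[seq_len(n_s)] != 1L)
    for (i in def_idx) {
      pid <- all_pid[i]
      st$deferrals[pid] <- st$deferrals[pid] + 1L
      s <- SPECIALTIES[st$spec_i[pid]]
      if (st$acu_i[pid] == 1L) wl[[s]]$semi <- c(pid, wl[[s]]$semi)
      else wl[[s]]$deferred <- c(wl[[s]]$deferred, pid)
    }

    if (d > warm_days) {
      acc[[length(acc) + 1L]] <- list(
        pid = all_pid, day = rep(d, length(all_pid)),
        week = rep((d - warm_days - 1L) %/% 7L + 1L, length(all_pid)),
        room = res$room + 1L,
        scheduled = c(rep(TRUE, n_s), rep(FALSE, length(bp$pid))),
        planned_start = c(sp$planned_start, rep(NA_real_, length(bp$pid))),
        ref_start = c(sp$planned_start, bp$ready),
        ind_start = res$ind_start, room_enter = res$room_enter,
        proc_start = res$proc_start, room_exit = res$room_exit,
        clean_end = res$clean_end,
        treated = dispo == 1L)
      room_acc[[length(room_acc) + 1L]] <- list(
        day = rep(d, n_rooms), week = rep((d - warm_days - 1L) %/% 7L + 1L, n_rooms),
        room = seq_len(n_rooms), open = meta$open == 1L,
        is_er = meta$is_er == 1L,
        elective_room = meta$open == 1L & meta$dept >= 0L,
        last_end = res$room_last_end)
    }

    # ---- freeze tomorrow's schedules in the evening ----
    if (d < total_days) {
      wd_next <- (d %% 7L) + 1L
      if (wd_next <= 5L) {
        built <- build_day_schedules(store_view(st), wl, mss, wd_next,
                                     scenario, calib)
        frozen <- built$schedules
        wl <- built$wl
      } else {
        frozen <- list()
      }
    }
  }

  cases <- finalize_cases(acc, st)
  rooms_df <- finalize_rooms(room_acc, rooms)
  structure(list(cases = cases, rooms = rooms_df,
                 horizon_weeks = horizon_weeks, warmup_weeks = warmup_weeks,
                 scenario = scenario$label, seed = seed,
                 n_generated = st$n),
            class = "or_replication")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten the frozen per-room schedules into executor vectors
flatten_schedules <- function(frozen, rooms, st) {
  out <- list(pid = integer(0), room = integer(0), planned_start = numeric(0),
              planned_len = numeric(0), dept = integer(0),
              induction = numeric(0), occupation = numeric(0),
              cleaning = numeric(0))
  if (length(frozen) == 0) return(out)
  pid <- integer(0); room <- integer(0)
  pstart <- numeric(0); plen <- numeric(0)
  for (r in names(frozen)) {
    sc <- frozen[[r]]
    if (nrow(sc) == 0) next
    ri <- match(r, rooms) - 1L
    pid <- c(pid, sc$pid)
    room <- c(room, rep(ri, nrow(sc)))
    pstart <- c(pstart, sc$planned_start)
    plen <- c(plen, sc$planned_len)
  }
  list(pid = pid, room = room, planned_start = pstart, planned_len = plen,
       dept = st$spec_i[pid] - 1L,
       induction = st$induction[pid],
       occupation = st$occupation[pid],
       cleaning = st$cleaning[pid])
}

breakin_inputs <- function(calib, st, ids, d, lead) {
  if (length(ids) == 0) {
    return(list(pid = integer(0), ptype = integer(0), dept = integer(0),
                notice = numeric(0), ready = numeric(0), deadline = numeric(0),
                induction = numeric(0), occupation = numeric(0),
                cleaning = numeric(0), planned_len = numeric(0)))
  }
  notice <- st$arrival[ids] - (d - 1) * MIN_PER_DAY
  acu <- st$acu_i[ids]
  list(pid = ids,
       ptype = ifelse(acu == 3L, 3L, 2L),
       dept = st$spec_i[ids] - 1L,
       notice = notice,
       ready = notice + lead,
       deadline = ifelse(acu == 2L, notice + 360, 1e18),
       induction = st$induction[ids],
       occupation = st$occupation[ids],
       cleaning = st$cleaning[ids],
       planned_len = breakin_plen(calib, st$spec_i[ids], acu, st$cls_i[ids]))
}

finalize_cases <- function(acc, st) {
  if (length(acc) == 0) {
    return(data.frame(pid = integer(0)))
  }
  cols <- names(acc[[1]])
  out <- lapply(setNames(cols, cols), function(cl)
    unlist(lapply(acc, `[[`, cl), use.names = FALSE))
  df <- as.data.frame(out)
  df$induction_dur <- st$induction[df$pid]
  df$specialty <- SPECIALTIES[st$spec_i[df$pid]]
  df$acuity <- names(ACUITY_INT)[st$acu_i[df$pid] + 1L]
  df$class <- DURATION_CLASSES[st$cls_i[df$pid]]
  df$disposition <- ifelse(df$treated, "treated", "deferred")
  df$waiting <- ifelse(df$treated, pmax(0, df$room_enter - df$ref_start),
                       NA_real_)
  df
}

finalize_rooms <- function(room_acc, rooms) {
  if (length(room_acc) == 0) return(data.frame(day = integer(0)))
  cols <- names(room_acc[[1]])
  out <- lapply(setNames(cols, cols), function(cl)
    unlist(lapply(room_acc, `[[`, cl), use.names = FALSE))
  df <- as.data.frame(out)
  df$room_id <- rooms[df$room]
  df
}

#' @export
print.or_replication <- function(x, ...) {
  tr <- sum(x$cases$treated)
  cat("Replication of scenario '", x$scenario, "' (seed ", x$seed, ")\n",
      sep = "")
  cat("  ", x$horizon_weeks, " weeks measured: ", tr, " treated, ",
      sum(!x$cases$treated), " deferral events\n", sep = "")
  invisible(x)
}
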