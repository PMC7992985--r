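# A hand-built one-day replication object with exactly known indicators.
fake_rep <- function(cases, rooms, weeks = 1) {
  structure(list(cases = cases, rooms = rooms, horizon_weeks = weeks,
                 warmup_weeks = 0, scenario = "toy", seed = 1),
            class = "or_replication")
}

toy_case <- function(pid, day = 1, room = 1, acuity = "elective",
                     scheduled = TRUE, planned_start = NA, ref_start = NA,
                     ind_start = NA, room_enter = NA, proc_start = NA,
                     room_exit = NA, clean_end = NA, treated = TRUE,
                     induction_dur = NA) {
  data.frame(pid = pid, day = day, week = 1, room = room,
             scheduled = scheduled, planned_start = planned_start,
             ref_start = ref_start, ind_start = ind_start,
             room_enter = room_enter, proc_start = proc_start,
             room_exit = room_exit, clean_end = clean_end,
             treated = treated, induction_dur = induction_dur,
             specialty = "GVT", acuity = acuity, class = "medium",
             disposition = ifelse(treated, "treated", "deferred"),
             waiting = ifelse(treated, pmax(0, room_enter - ref_start),
                              NA_real_))
}

toy_rooms <- function(days = 1, rooms = 1) {
  expand.grid(day = seq_len(days), room = rooms) |>
    transform(week = 1, open = TRUE, is_er = FALSE, elective_room = TRUE,
              last_end = NA_real_)
}

test_that("waiting time is the planned-to-actual delay, clipped at zero", {
  cases <- rbind(
    toy_case(1, planned_start = 540, ref_start = 540, ind_start = 565,
             room_enter = 565, proc_start = 595, room_exit = 695,
             clean_end = 710, induction_dur = 30),
    toy_case(2, planned_start = 710, ref_start = 710, ind_start = 700,
             room_enter = 700, proc_start = 730, room_exit = 800,
             clean_end = 815, induction_dur = 30))
  r <- fake_rep(cases, toy_rooms())
  k <- compute_kpis(r)
  # patient 1 waits 25 min; patient 2 starts early and waits 0
  expect_equal(k$waiting_elective, 12.5)
})

test_that("a deferred patient's waiting restarts from the updated plan", {
  cases <- rbind(
    toy_case(1, day = 1, treated = FALSE),                     # deferred
    toy_case(1, day = 2, planned_start = 510, ref_start = 510,
             ind_start = 550, room_enter = 550, proc_start = 580,
             room_exit = 680, clean_end = 695, induction_dur = 30))
  r <- fake_rep(cases, toy_rooms(days = 2))
  k <- compute_kpis(r)
  expect_equal(k$waiting_elective, 40)    # day-1 delay is not counted
  expect_equal(k$deferrals_per_week, 1)
  expect_equal(k$treated_per_week, 1)
})

test_that("overtime and undertime are exclusive and measured against 15:45", {
  mk <- function(clean_end) {
    cases <- toy_case(1, ind_start = 510, room_enter = 510, proc_start = 540,
                      room_exit = clean_end - 15, clean_end = clean_end,
                      planned_start = 510, ref_start = 510,
                      induction_dur = 30)
    fake_rep(cases, toy_rooms())
  }
  expect_equal(unlist(over_undertime(mk(970))[c("overtime", "undertime")]),
               c(overtime = 25, undertime = 0))
  expect_equal(unlist(over_undertime(mk(920))[c("overtime", "undertime")]),
               c(overtime = 0, undertime = 25))
  # an empty room-day is pure undertime over the whole regular window
  empty <- fake_rep(toy_case(1, treated = FALSE), toy_rooms())
  expect_equal(over_undertime(empty)$undertime, 435)
  # exclusivity on a realistic run
  rep_ <- run_replication(scenario_config(), horizon_weeks = 2,
                          warmup_weeks = 1, seed = 31)
  ou <- over_undertime(rep_)
  expect_true(all(ou$overtime == 0 | ou$undertime == 0))
})

test_that("room and system utilization follow the interval definitions", {
  # sequential chain fully inside regular hours: induction 30 in room,
  # occupation 300, cleaning 15
  cases <- toy_case(1, ind_start = 510, room_enter = 510, proc_start = 540,
                    room_exit = 840, clean_end = 855, planned_start = 510,
                    ref_start = 510, induction_dur = 30)
  r <- fake_rep(cases, toy_rooms())
  expect_equal(utilization(r, "room", "regular"), 315 / 435)
  expect_equal(utilization(r, "system", "regular"), 345 / 435)
  expect_equal(utilization(r, "room", "extended"), 0)
  # an empty day utilizes nothing
  r0 <- fake_rep(toy_case(1, treated = FALSE), toy_rooms())
  expect_equal(utilization(r0, "room", "regular"), 0)
  expect_equal(utilization(r0, "system", "regular"), 0)
})

test_that("busy minutes add up across the regular and extended windows", {
  rep_ <- run_replication(scenario_config(buffer_hours = 3),
                          horizon_weeks = 2, warmup_weeks = 1, seed = 32)
  n_rd <- sum(rep_$rooms$elective_room)
  busy_split <- utilization(rep_, "room", "regular") * 435 * n_rd +
    utilization(rep_, "room", "extended") * 255 * n_rd
  el_key <- with(rep_$rooms[rep_$rooms$elective_room, ], paste(day, room))
  tr <- rep_$cases[rep_$cases$treated, ]
  tr <- tr[paste(tr$day, tr$room) %in% el_key, ]
  busy_total <- sum(pmax(0, pmin(tr$clean_end, 1200) -
                           pmax(tr$proc_start, 510)))
  expect_equal(busy_split, busy_total, tolerance = 1e-10)
})

test_that("anesthesia turnover averages exit-to-next-procedure gaps", {
  cases <- rbind(
    toy_case(1, ind_start = 510, room_enter = 510, proc_start = 540,
             room_exit = 600, clean_end = 614, planned_start = 510,
             ref_start = 510, induction_dur = 30),
    toy_case(2, ind_start = 614, room_enter = 614, proc_start = 628,
             room_exit = 700, clean_end = 715, planned_start = 614,
             ref_start = 614, induction_dur = 14))
  r <- fake_rep(cases, toy_rooms())
  expect_equal(anesthesia_turnover(r), 28)   # 628 - 600
  # a single-case day is excluded entirely
  r1 <- fake_rep(cases[1, ], toy_rooms())
  expect_true(is.na(anesthesia_turnover(r1)))
})

test_that("replication aggregation gives exact t-intervals", {
  kpis <- data.frame(treated_per_week = c(10, 12, 14))
  ci <- aggregate_replications(kpis)
  expect_equal(ci$mean, 12)
  # closed form: t(0.975, 2) * sd / sqrt(3)
  expect_equal(ci$half_width, qt(0.975, 2) * 2 / sqrt(3))
  expect_equal(ci$half_width, 4.96823, tolerance = 1e-5)
  # identical replications give zero-width intervals
  ci0 <- aggregate_replications(data.frame(x = c(3, 3, 3, 3)))
  expect_equal(ci0$half_width, 0)
  # a single replication yields a mean but no interval
  ci1 <- aggregate_replications(data.frame(x = 5))
  expect_equal(ci1$mean, 5)
  expect_true(is.na(ci1$half_width))
})

test_that("interval overlap flags match the non-overlap significance rule", {
  expect_false(ci_overlap(list(lower = 1, upper = 2),
                          list(lower = 3, upper = 4)))
  expect_true(ci_overlap(list(lower = 1, upper = 3.5),
                         list(lower = 3, upper = 4)))
  d <- contrast_ci(c(5, 6, 7, 8), c(1, 2, 3, 4))
  expect_equal(d$mean, 4)
  expect_equal(d$lower, 4)  # constant paired difference: zero-width interval
})

test_that("confidence interval width shrinks with the replication count", {
  sc <- scenario_config()
  set.seed(1)
  k <- run_scenario(sc, replications = 8, horizon_weeks = 2,
                    warmup_weeks = 1, base_seed = 100)
  ci4 <- aggregate_replications(k[1:4, ])
  ci8 <- aggregate_replications(k)
  hw4 <- ci4$half_width[ci4$kpi == "treated_per_week"]
  hw8 <- ci8$half_width[ci8$kpi == "treated_per_week"]
  expect_lt(hw8, hw4 * 1.2)  # on average ~ 1/sqrt(n); allow sampling slack
})
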