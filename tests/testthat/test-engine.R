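# Engine tests work on two levels: hand-checkable single-day traces through
# the intraday executor, and full replications under degenerate calibrations
# whose outcomes are known exactly.

test_that("a deterministic serial day matches the brute-force oracle", {
  ind <- c(40, 40); occ <- c(145, 145); cln <- c(15, 15)
  sched <- toy_sched(room = c(0, 0), planned_start = c(510, 710),
                     planned_len = c(200, 200),
                     induction = ind, occupation = occ, cleaning = cln)
  res <- run_toy_day(toy_meta(1), sched)
  orc <- oracle_single_room_day(ind, occ, cln, planned_len = c(200, 200))
  expect_equal(res$room_enter, orc$enter)
  expect_equal(res$proc_start, orc$proc)
  expect_equal(res$room_exit, orc$exit)
  expect_equal(res$clean_end, orc$clean)
  expect_identical(res$disposition, c(1L, 1L))
  expect_equal(res$room_last_end, 910)
})

test_that("a pending case projected past the close is deferred, started cases finish", {
  # first case overruns to 946; the second cannot start after the close
  sched <- toy_sched(room = c(0, 0), planned_start = c(510, 710),
                     planned_len = c(200, 200),
                     induction = c(40, 40), occupation = c(381, 145),
                     cleaning = c(15, 15))
  res <- run_toy_day(toy_meta(1), sched)
  expect_identical(res$disposition, c(1L, 2L))
  expect_equal(res$clean_end[1], 946)  # started cases always complete
  orc <- oracle_single_room_day(c(40, 40), c(381, 145), c(15, 15),
                                planned_len = c(200, 200))
  expect_identical(orc$deferred, c(FALSE, TRUE))

  # a 2 h buffer is still too short (projected end 1146 > 1065): deferred
  res2 <- run_toy_day(toy_meta(1), sched,
                      scenario = scenario_config(buffer_hours = 2))
  expect_identical(res2$disposition, c(1L, 2L))
  # a 4 h buffer fits the pending case, which is treated in the buffer
  res4 <- run_toy_day(toy_meta(1), sched,
                      scenario = scenario_config(buffer_hours = 4))
  expect_identical(res4$disposition, c(1L, 1L))
  expect_equal(res4$room_enter[2], 946)
  orc2 <- oracle_single_room_day(c(40, 40), c(381, 145), c(15, 15),
                                 planned_len = c(200, 200), eff_close = 1065)
  expect_identical(orc2$deferred, c(FALSE, TRUE))
  orc4 <- oracle_single_room_day(c(40, 40), c(381, 145), c(15, 15),
                                 planned_len = c(200, 200), eff_close = 1185)
  expect_identical(orc4$deferred, c(FALSE, FALSE))
})

test_that("an emergency breaks into the earliest-available staffed room", {
  # two busy rooms: current cases end (incl. cleaning) at 710 and 910
  sched <- toy_sched(room = c(0, 1), planned_start = c(510, 510),
                     planned_len = c(200, 400),
                     induction = c(40, 40), occupation = c(145, 345),
                     cleaning = c(15, 15))
  brk <- toy_breakin(pid = 3L, type = 3L, notice = 600,
                     induction = 30, occupation = 100, cleaning = 15,
                     planned_len = 145)
  res <- run_toy_day(toy_meta(2), sched, brk)
  expect_identical(res$room[3], 0L)       # argmin over projected entry
  expect_equal(res$room_enter[3], 710)    # current case end + cleaning
  expect_identical(res$disposition[3], 1L)

  # an idle dedicated emergency room takes it immediately instead
  sched_er <- toy_sched(room = c(0, 1), planned_start = c(510, 510),
                        planned_len = c(200, 400),
                        induction = c(40, 40), occupation = c(145, 345),
                        cleaning = c(15, 15))
  res2 <- run_toy_day(toy_meta(2, er = TRUE), sched_er, brk)
  expect_identical(res2$room[3], 2L)
  expect_equal(res2$room_enter[3], 600)   # waiting zero past ready
})

test_that("emergency insertion postpones the pending plan and can cause deferral", {
  # room 0: three short cases planned back-to-back, ending well before close
  sched <- toy_sched(room = c(0, 0, 0), planned_start = c(510, 650, 790),
                     planned_len = c(140, 140, 140),
                     induction = c(25, 25, 25), occupation = c(100, 100, 100),
                     cleaning = c(15, 15, 15))
  brk <- toy_breakin(pid = 4L, type = 3L, notice = 520,
                     induction = 30, occupation = 200, cleaning = 15,
                     planned_len = 245)
  res <- run_toy_day(toy_meta(1), sched, brk)
  # emergency enters after case 1 (clean end 650), cases 2-3 shift by 245
  expect_equal(res$room_enter[4], 650)
  expect_equal(res$room_enter[2], 650 + 245)
  # case 3 would now start at 1140 >= close and is deferred
  expect_identical(res$disposition, c(1L, 1L, 2L, 1L))
})

test_that("parallel induction overlaps exactly when a team is free", {
  sc_par <- scenario_config(parallel_induction = TRUE, extra_teams = 1L)
  ind <- c(30, 30); occ <- c(120, 120); cln <- c(15, 15)
  sched <- toy_sched(room = c(0, 0), planned_start = c(510, 645),
                     planned_len = c(135, 135),
                     induction = ind, occupation = occ, cleaning = cln)
  res <- run_toy_day(toy_meta(1), sched, scenario = sc_par)
  # first patient of the session is not overlapped: in-room chain
  expect_equal(res$room_enter[1], 510)
  expect_equal(res$proc_start[1], 540)
  # successor inducted in parallel from the predecessor's room entry; the
  # room is reoccupied the moment cleaning finishes, saving the induction
  expect_equal(res$ind_start[2], 510)           # at predecessor room entry
  expect_equal(res$room_enter[2], 510 + 30 + 120 + 15)
  expect_equal(res$proc_start[2], res$room_enter[2])

  # sequential control: successor starts only after the full serial chain
  res_seq <- run_toy_day(toy_meta(1), sched)
  expect_equal(res_seq$room_enter[2], 675)
  expect_equal(res_seq$proc_start[2], 705)
  expect_equal(res_seq$proc_start[2] - res_seq$proc_start[1],
               30 + 120 + 15)  # induction + occupation + cleaning cadence
})

test_that("without a free team parallel mode degrades to the serial chain", {
  sc_par0 <- scenario_config(parallel_induction = TRUE, extra_teams = 0L)
  sched <- toy_sched(room = c(0, 0), planned_start = c(510, 645),
                     planned_len = c(135, 135),
                     induction = c(30, 30), occupation = c(120, 120),
                     cleaning = c(15, 15))
  # no emergency room in the layout, so no team can be borrowed
  res <- run_toy_day(toy_meta(1), sched, scenario = sc_par0)
  res_seq <- run_toy_day(toy_meta(1), sched)
  expect_equal(res$room_enter, res_seq$room_enter)
  expect_equal(res$proc_start, res_seq$proc_start)

  # with the dedicated emergency room idle, its team is borrowed and the
  # overlap happens after all
  res_er <- run_toy_day(toy_meta(1, er = TRUE), sched, scenario = sc_par0)
  expect_lt(res_er$proc_start[2], res_seq$proc_start[2])
})

test_that("identical seeds reproduce a replication exactly", {
  sc <- scenario_config()
  a <- run_replication(sc, horizon_weeks = 2, warmup_weeks = 1, seed = 11)
  b <- run_replication(sc, horizon_weeks = 2, warmup_weeks = 1, seed = 11)
  expect_identical(a$cases, b$cases)
  expect_identical(a$rooms, b$rooms)
  expect_false(identical(
    a$cases,
    run_replication(sc, horizon_weeks = 2, warmup_weeks = 1, seed = 12)$cases))
})

test_that("zero demand produces an empty log", {
  calib <- calibration(arrival = quiet_arrivals(), weekly_volume = 0)
  rep_ <- run_replication(scenario_config(), calib, horizon_weeks = 2,
                          warmup_weeks = 0, seed = 1)
  expect_identical(nrow(rep_$cases), 0L)
})

test_that("degenerate calibration executes the plan to the minute", {
  # all dispersions zero, no urgent/emergency arrivals: the realized
  # timeline must equal the frozen plan exactly
  calib <- det_calibration(weekly_volume = 220)
  sc <- scenario_config()
  rep_ <- run_replication(sc, calib, horizon_weeks = 4, warmup_weeks = 1,
                          seed = 5)
  cases <- rep_$cases
  expect_gt(nrow(cases), 100)
  expect_true(all(cases$treated))
  expect_equal(cases$room_enter, cases$planned_start)
  expect_true(all(cases$waiting == 0))
  ou <- over_undertime(rep_)
  expect_true(all(ou$overtime == 0))
})

test_that("with zero induction time parallel and sequential modes coincide", {
  dm <- duration_model(induction_fraction = 0)
  calib <- calibration(duration = dm)
  seq_ <- run_replication(scenario_config(), calib,
                          horizon_weeks = 3, warmup_weeks = 1, seed = 9)
  par_ <- run_replication(
    scenario_config(parallel_induction = TRUE, extra_teams = 2L), calib,
    horizon_weeks = 3, warmup_weeks = 1, seed = 9)
  expect_identical(seq_$cases, par_$cases)
})

test_that("every scheduled patient is conserved and rooms host one case at a time", {
  rep_ <- run_replication(scenario_config(), horizon_weeks = 3,
                          warmup_weeks = 1, seed = 21)
  cases <- rep_$cases
  # conservation: exactly one disposition per patient-day
  expect_true(all(cases$disposition %in% c("treated", "deferred")))
  expect_false(any(duplicated(cases[c("pid", "day")])))
  # resource safety: cases in the same room on the same day never overlap
  tr <- cases[cases$treated, ]
  tr <- tr[order(tr$day, tr$room, tr$room_enter), ]
  same <- tr$day[-1] == tr$day[-nrow(tr)] & tr$room[-1] == tr$room[-nrow(tr)]
  gap <- tr$room_enter[-1] - tr$clean_end[-nrow(tr)]
  expect_true(all(gap[same] > -1e-6))
  # timestamps are ordered along the chain for every treated patient
  expect_true(all(tr$ind_start <= tr$proc_start + 1e-9))
  expect_true(all(tr$room_enter <= tr$proc_start + 1e-9))
  expect_true(all(tr$proc_start < tr$room_exit))
  expect_true(all(tr$room_exit < tr$clean_end))
  # deferred patients reappear on a later day's program
  def <- cases[!cases$treated & cases$day < max(cases$day) - 7, ]
  if (nrow(def) > 0) {
    reappears <- vapply(seq_len(nrow(def)), function(i)
      any(cases$pid == def$pid[i] & cases$day > def$day[i]), logical(1))
    expect_true(all(reappears))
  }
})

test_that("night arrivals are served by the night rooms after hours", {
  # a very-urgent case at 23:00 with empty day schedules must end up in a
  # night room (R16/R17), not a closed elective room
  calib <- det_calibration()
  mss <- single_room_mss("GVT")
  sc <- scenario_config()
  meta <- orsim:::room_meta(mss, sc)[[1]]
  brk <- toy_breakin(pid = 1L, type = 2L, notice = 1380,
                     induction = 20, occupation = 80, cleaning = 10,
                     planned_len = 110, dept = 0L)
  res <- orsim:::exec_day(meta, numeric(18), orsim:::flatten_schedules(
    list(), sprintf("R%02d", 1:18), NULL), brk, sc)
  expect_identical(res$disposition[1], 1L)
  expect_true(res$room[1] %in% c(15L, 16L))  # 0-based: R16 or R17
  expect_equal(res$room_enter[1], 1380)
})
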