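#' Master surgery schedule (MSS)
#'
#' The MSS is the weekly cyclic assignment of operating-room days to medical
#' departments: a table with one row per (weekday, room) giving the
#' department that books the room that day, or `"EMERGENCY"` for the
#' dedicated emergency room, or `"CLOSED"`. The theatre has 18 rooms; in the
#' Base Case exactly one room per weekday is the dedicated emergency room,
#' and two rooms additionally run throughout the night for very-urgent and
#' emergency cases.
#'
#' `default_mss()` ships a deterministic layout allocating the 85 elective
#' room-days per week across the nine departments roughly in proportion to
#' their caseloads (trauma and general/visceral surgery largest), with room
#' R18 reserved for emergencies every day and rooms R16/R17 as night rooms.
#' Any other layout can be supplied as a CSV via [read_mss()].
#'
#' @return data.frame with columns `weekday` (1-5, Monday-Friday), `room_id`,
#'   `department`; attributes `night_rooms` (two room ids) and
#'   `emergency_room` (one room id).
#' @export
default_mss <- function() {
  rooms <- sprintf("R%02d", 1:18)
  wd <- 1:5
  grid <- expand.grid(weekday = wd, room_id = rooms,
                      stringsAsFactors = FALSE)
  # weekly room-day allocation (85 elective room-days):
  # TS 14, GVT 13, GYN 11, VS 9, CAR 8, NS 8, PED 8, URO 8, OMS 6
  assign_room <- function(room, weekday) {
    switch(room,
      R01 = , R02 = "TS",
      R03 = if (weekday <= 4) "TS" else "GVT",
      R04 = , R05 = "GVT",
      R06 = if (weekday <= 2) "GVT" else "GYN",
      R07 = "GYN",
      R08 = if (weekday <= 3) "GYN" else "CAR",
      R09 = "CAR",
      R10 = if (weekday == 1) "CAR" else "VS",
      R11 = "VS",
      R12 = "NS",
      R13 = if (weekday <= 3) "NS" else "PED",
      R14 = "PED",
      R15 = if (weekday == 1) "PED" else "OMS",
      R16 = if (weekday <= 2) "OMS" else "URO",
      R17 = "URO",
      R18 = "EMERGENCY")
  }
  grid$department <- mapply(assign_room, grid$room_id, grid$weekday)
  grid <- grid[order(grid$weekday, grid$room_id), ]
  rownames(grid) <- NULL
  attr(grid, "night_rooms") <- c("R16", "R17")
  attr(grid, "emergency_room") <- "R18"
  class(grid) <- c("or_mss", "data.frame")
  validate_mss(grid)
}

#' Validate a master surgery schedule
#'
#' Checks the structural invariants: 18 rooms, five weekdays, exactly one
#' dedicated emergency room per weekday (the same room every day), exactly
#' two night rooms, and department codes drawn from [SPECIALTIES] (plus
#' `"EMERGENCY"`/`"CLOSED"`).
#'
#' @param mss data.frame as returned by [default_mss()] or [read_mss()].
#' @return the validated `mss`, invisibly classed as `or_mss`.
#' @export
validate_mss <- function(mss) {
  stopifnot(is.data.frame(mss),
            all(c("weekday", "room_id", "department") %in% names(mss)))
  rooms <- sort(unique(mss$room_id))
  if (length(rooms) != 18) stop("an MSS must cover exactly 18 operating rooms")
  if (!setequal(unique(mss$weekday), 1:5)) {
    stop("an MSS must cover weekdays 1-5")
  }
  if (nrow(mss) != 90) stop("an MSS must have one row per (weekday, room)")
  ok <- mss$department %in% c(SPECIALTIES, "EMERGENCY", "CLOSED")
  if (!all(ok)) {
    stop("unknown department code(s): ",
         paste(unique(mss$department[!ok]), collapse = ", "))
  }
  er <- unique(mss$room_id[mss$department == "EMERGENCY"])
  per_day <- tapply(mss$department == "EMERGENCY", mss$weekday, sum)
  if (length(er) != 1 || any(per_day != 1)) {
    stop("exactly one dedicated emergency room per weekday is required")
  }
  night <- attr(mss, "night_rooms")
  if (is.null(night)) {
    night <- setdiff(rooms, er)[17:18]  # fall back: last two elective rooms
    attr(mss, "night_rooms") <- night
  }
  if (length(night) != 2 || !all(night %in% rooms)) {
    stop("an MSS must designate exactly two night rooms")
  }
  attr(mss, "emergency_room") <- er
  if (!inherits(mss, "or_mss")) class(mss) <- c("or_mss", class(mss))
  invisible(mss)
}

#' Read / write an MSS as CSV
#'
#' The CSV has columns `weekday` (1-5), `room_id`, `department`. Night rooms
#' can be flagged with an optional logical `night_room` column; otherwise
#' the two highest-numbered non-emergency rooms are used.
#'
#' @param path file path.
#' @return for `read_mss`, a validated `or_mss`.
#' @export
read_mss <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("night_room" %in% names(df)) {
    attr(df, "night_rooms") <- sort(unique(df$room_id[as.logical(df$night_room)]))
    df$night_room <- NULL
  }
  validate_mss(df)
}

#' @param mss an `or_mss`.
#' @rdname read_mss
#' @export
write_mss <- function(mss, path) {
  out <- as.data.frame(mss)
  out$night_room <- out$room_id %in% attr(mss, "night_rooms")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.or_mss <- function(x, ...) {
  rd <- table(x$department[x$department %in% SPECIALTIES])
  cat("Master surgery schedule: 18 rooms x 5 weekdays\n")
  cat("  emergency room:", attr(x, "emergency_room"),
      "| night rooms:", paste(attr(x, "night_rooms"), collapse = ", "), "\n")
  cat("  elective room-days/week:",
      paste(names(rd), as.integer(rd), sep = "=", collapse = " "), "\n")
  invisible(x)
}

# weekly elective room-days per department
mss_roomdays <- function(mss) {
  tab <- table(factor(mss$department, levels = SPECIALTIES))
  setNames(as.integer(tab), SPECIALTIES)
}
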