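#' Surgery duration model
#'
#' Parameterizes all per-case durations. The anchor quantities are the mean
#' "presence of anesthesiologist" times of elective patients per specialty
#' and duration class (short/medium/long): presence spans anesthesia
#' induction through patient transfer and is the room-blocking time per case
#' under sequential induction. Presence is decomposed into an induction
#' component (default 20%) and an in-room occupation component (default 80%),
#' each sampled log-normally; under parallel induction only occupation (plus
#' cleaning) blocks the operating room. Cardiac surgery (CAR) occupation
#' times are drawn from a two-component log-normal mixture, reflecting the
#' bimodal shape of observed cardiac durations; all other specialties use a
#' single right-skewed log-normal.
#'
#' Urgent patients (semi- and very-urgent) use their specialty's medium-class
#' means. Emergency durations are longer and more variable than elective
#' ones: class means are scaled by `emergency_mean_mult` and coefficients of
#' variation by `emergency_cv_mult`.
#'
#' @param presence_mean 9 x 3 numeric matrix of mean elective presence times
#'   in minutes, rows named by [SPECIALTIES], columns
#'   `c("short","medium","long")`.
#' @param class_mix probabilities that a generated elective case is
#'   short/medium/long. The default is weighted towards short cases, as in
#'   right-skewed empirical theatre case-mixes, and sized so that the planned
#'   weekly elective load slightly exceeds bookable regular-hours capacity.
#' @param cv coefficient of variation of the log-normal induction and
#'   occupation components (0 gives degenerate, deterministic durations).
#' @param induction_fraction share of presence attributed to anesthesia
#'   induction; the remainder is in-room occupation.
#' @param cleaning_mean,cleaning_cv log-normal cleaning (turnover
#'   preparation) time parameters, minutes.
#' @param emergency_mean_mult,emergency_cv_mult scaling of mean and CV for
#'   emergency cases relative to electives.
#' @param car_mix two-component mixture settings for CAR occupation times:
#'   `offset` places the component means at (1 +/- offset) times the class
#'   mean, `cv` is the within-component CV, `weight` the probability of the
#'   lower component.
#' @return an object of class `or_duration_model`.
#' @export
duration_model <- function(presence_mean = default_presence_means(),
                           class_mix = c(short = 0.62, medium = 0.27, long = 0.11),
                           cv = 0.5,
                           induction_fraction = 0.2,
                           cleaning_mean = 15,
                           cleaning_cv = 0.3,
                           emergency_mean_mult = 1.2,
                           emergency_cv_mult = 1.3,
                           car_mix = list(offset = 0.4, cv = 0.25, weight = 0.5)) {
  stopifnot(is.matrix(presence_mean),
            identical(rownames(presence_mean), SPECIALTIES),
            identical(colnames(presence_mean), DURATION_CLASSES),
            all(presence_mean > 0))
  if (any(presence_mean[, "short"] >= presence_mean[, "medium"]) ||
      any(presence_mean[, "medium"] >= presence_mean[, "long"])) {
    stop("class means must increase short < medium < long for every specialty")
  }
  class_mix <- class_mix / sum(class_mix)
  stopifnot(length(class_mix) == 3, all(class_mix >= 0),
            cv >= 0, cleaning_cv >= 0, cleaning_mean >= 0,
            induction_fraction >= 0, induction_fraction < 1,
            emergency_mean_mult > 0, emergency_cv_mult > 0)
  m <- structure(
    list(presence_mean = presence_mean,
         class_mix = class_mix,
         cv = cv,
         induction_fraction = induction_fraction,
         cleaning_mean = cleaning_mean,
         cleaning_cv = cleaning_cv,
         emergency_mean_mult = emergency_mean_mult,
         emergency_cv_mult = emergency_cv_mult,
         car_mix = car_mix),
    class = "or_duration_model")
  m$class_thresholds <- class_thresholds(m)
  m
}

#' Default mean presence-of-anesthesiologist times (minutes)
#'
#' Mean elective anesthesia presence per specialty and duration class used
#' for calibration and scheduling, e.g. 74/166/371 minutes for GVT
#' short/medium/long cases.
#' @return 9 x 3 matrix.
#' @export
default_presence_means <- function() {
  matrix(c(
     74, 166, 371,   # GVT
     46, 135, 334,   # VS
     44, 101, 322,   # GYN
     63, 204, 324,   # CAR
     40,  97, 256,   # PED
     55, 137, 307,   # OMS
     81, 194, 406,   # NS
     63, 134, 288,   # TS
     94, 210, 375),  # URO
    nrow = 9, byrow = TRUE,
    dimnames = list(SPECIALTIES, DURATION_CLASSES))
}

#' @export
print.or_duration_model <- function(x, ...) {
  cat("Duration model: log-normal components, CV", x$cv, "\n")
  cat("  class mix (short/medium/long):",
      paste(round(x$class_mix, 3), collapse = "/"), "\n")
  cat("  induction fraction", x$induction_fraction,
      "| cleaning mean", x$cleaning_mean, "min\n")
  cat("  emergency scaling: mean x", x$emergency_mean_mult,
      ", CV x", x$emergency_cv_mult, "\n")
  invisible(x)
}

# log-normal sampler parameterized by mean and coefficient of variation;
# cv = 0 degenerates to the mean exactly
rlnorm_mcv <- function(n, mean, cv) {
  if (mean <= 0) return(rep(0, n))
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# mean presence / cv for a (specialty, acuity, class) combination
presence_pars <- function(model, specialty, acuity, class) {
  if (acuity %in% c("semi_urgent", "very_urgent")) class <- "medium"
  m <- model$presence_mean[specialty, class]
  cv <- model$cv
  if (acuity == "emergency") {
    m <- m * model$emergency_mean_mult
    cv <- cv * model$emergency_cv_mult
  }
  c(mean = unname(m), cv = cv)
}

#' Sample per-case durations
#'
#' Draws induction, operating-room occupation and cleaning durations for `n`
#' cases of one (specialty, acuity, class) combination. Induction and
#' occupation together form the anesthesia presence time, whose mean under
#' default calibration equals the configured class mean (times the emergency
#' multiplier for emergencies).
#'
#' @param model an [or_duration_model][duration_model()].
#' @param specialty one of [SPECIALTIES].
#' @param acuity one of `"elective"`, `"semi_urgent"`, `"very_urgent"`,
#'   `"emergency"`.
#' @param class `"short"`, `"medium"` or `"long"`; ignored for urgents,
#'   which always use medium-class means.
#' @param n number of cases.
#' @return data.frame with columns `induction`, `occupation`, `cleaning`.
#' @export
sample_case_durations <- function(model, specialty, acuity, class, n = 1L) {
  stopifnot(inherits(model, "or_duration_model"))
  specialty <- match.arg(specialty, SPECIALTIES)
  acuity <- match.arg(acuity, ACUITIES)
  class <- match.arg(class, DURATION_CLASSES)
  pp <- presence_pars(model, specialty, acuity, class)
  ind_mean <- model$induction_fraction * pp["mean"]
  occ_mean <- (1 - model$induction_fraction) * pp["mean"]
  induction <- rlnorm_mcv(n, ind_mean, pp["cv"])
  if (specialty == "CAR") {
    cm <- model$car_mix
    lower <- runif(n) < cm$weight
    mw <- cm$weight * (1 - cm$offset) + (1 - cm$weight) * (1 + cm$offset)
    # rescale so the mixture mean equals occ_mean even for weight != 0.5
    lo <- occ_mean * (1 - cm$offset) / mw
    hi <- occ_mean * (1 + cm$offset) / mw
    comp_cv <- if (pp["cv"] <= 0) 0 else cm$cv
    occupation <- ifelse(lower, rlnorm_mcv(n, lo, comp_cv),
                         rlnorm_mcv(n, hi, comp_cv))
  } else {
    occupation <- rlnorm_mcv(n, occ_mean, pp["cv"])
  }
  cleaning <- rlnorm_mcv(n, model$cleaning_mean, model$cleaning_cv)
  data.frame(induction = induction, occupation = occupation,
             cleaning = cleaning)
}

# Tercile thresholds of the elective presence distribution per specialty,
# computed from the closed-form CDF of the class-mixture of log-normals
# (each class approximated by one log-normal at its class mean and model CV).
class_thresholds <- function(model) {
  w <- model$class_mix
  cv <- max(model$cv, 1e-6)
  sdlog <- sqrt(log1p(cv^2))
  th <- matrix(NA_real_, length(SPECIALTIES), 2,
               dimnames = list(SPECIALTIES, c("t1", "t2")))
  for (s in SPECIALTIES) {
    means <- model$presence_mean[s, ]
    meanlogs <- log(means) - sdlog^2 / 2
    cdf <- function(x) sum(w * stats::plnorm(x, meanlogs, sdlog))
    for (j in 1:2) {
      p <- j / 3
      th[s, j] <- uniroot(function(x) cdf(x) - p,
                          lower = 1, upper = max(means) * 10,
                          tol = 1e-6)$root
    }
  }
  th
}

#' Classify a forecast duration into short/medium/long
#'
#' Deterministic classification of a planned (forecast) presence duration
#' against per-specialty thresholds. By default the thresholds are the
#' terciles of the specialty's elective presence distribution, precomputed
#' when the duration model is built. The boundary convention is
#' inclusive-left: a duration exactly at a threshold falls in the lower
#' class.
#'
#' @param model an [or_duration_model][duration_model()].
#' @param specialty one of [SPECIALTIES].
#' @param planned_duration forecast presence duration(s), minutes.
#' @return character vector of classes.
#' @export
classify_duration_class <- function(model, specialty, planned_duration) {
  stopifnot(inherits(model, "or_duration_model"))
  specialty <- match.arg(specialty, SPECIALTIES)
  th <- unname(model$class_thresholds[specialty, ])
  if (th[1] >= th[2]) stop("class thresholds must satisfy t1 < t2")
  unname(ifelse(planned_duration <= th[1], "short",
                ifelse(planned_duration <= th[2], "medium", "long")))
}

# Expected presence / occupation / slot components used by the scheduler.
expected_presence <- function(model, specialty, acuity, class) {
  presence_pars(model, specialty, acuity, class)["mean"]
}
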