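---
title: "Simulating operating-theatre management policies with orsim"
author: "orsim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating operating-theatre management policies with orsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orsim)
```

## The system being modeled

orsim simulates the central operating theatre of a large multi-department
university hospital: 18 operating rooms shared by nine surgical departments
(general/visceral/transplant, vascular, gynecology, cardiac, pediatric,
oral/maxillofacial, neuro, trauma, and urological surgery), one room
dedicated to emergency patients and staffed around the clock, two rooms
whose night shift (22:00-06:00) handles very-urgent cases, and a pool of 13
anesthesia induction rooms. A master surgery schedule (MSS) assigns each
room-day to one department; departments book their own patients the evening
before execution, and an OR coordinator manages intraday disruptions.

Patients belong to four acuity classes with different planning rules:

* **elective** - booked ahead from the department's waiting list;
* **semi-urgent** - surgery within 24 h of arrival; placed at the head of
  the next day's program, never at night;
* **very-urgent** - surgery within 6 h; inserted intraday into a room of
  the own specialty when the window allows, otherwise into a night room or
  any available room;
* **emergency** - surgery as soon as possible; the dedicated emergency room
  if it is free, otherwise the staffed room with the earliest projected
  availability, whose pending patients are postponed accordingly.

Four management levers are evaluated against this Base Case: end-of-day
buffer hours (rooms stay staffed past the 15:45 close, up to 20:00, to
absorb delays - nothing is ever *planned* into the buffer), parallel
induction of anesthesia with 0-3 additional anesthesia teams, elective
sequencing (FIFO, shortest-first SF, longest-first LF), and closing the
dedicated emergency room.

## Synthetic input model

No patient-level dataset ships with the package; all inputs are generated
from printed summary statistics.

**Arrivals.** Urgent patients arrive per specialty with daytime
(06:00-22:00) weekday means summing to 12.6 per day (trauma surgery alone
4.7), and a total of 0.48 per night. Emergencies arrive regardless of
specialty: 2.8 per day window and 0.8 per night, every day of the week.
Counts are Poisson within each window (the printed standard deviations are
close to the Poisson value; a negative-binomial switch reproduces the
slight overdispersion of emergency counts but is off by default), and
arrival instants are uniform inside the window, since only per-window
counts are calibrated. Half of all urgent patients are very-urgent.
Daytime urgent rates are defined *per weekday*; applying them to weekends
as well would make the weekly volume and acuity-mix calibrations mutually
inconsistent.

**Durations.** The anchor quantities are the mean anesthesia presence
times (induction through transfer) of elective patients per specialty and
duration class, e.g. 74/166/371 minutes for short/medium/long
general-surgery cases. Presence is split into a log-normal induction
component (20% of the mean by default) and a log-normal in-room occupation
component (80%), both with coefficient of variation 0.5 - surgical
durations are strongly right-skewed. Cardiac occupation times come from a
two-component log-normal mixture (components at 0.6 and 1.4 times the
class mean, equal weights), reflecting the bimodal mix of short
catheter-type and long open-heart procedures. Cleaning is log-normal with
mean 15 min (CV 0.3). Urgent patients use their specialty's medium-class
means; emergencies scale the elective means by 1.2 and the CV by 1.3,
since observed emergency durations are longer and more variable.

**Volume calibration.** The weekly demand target is 345 surgeries. With
the printed urgent and emergency rates this implies 253.4 elective arrivals
per week (73.5% of all patients - the nominal 72/21/7 acuity split is
reproduced to within 1.5 percentage points; exactly 72% is not jointly
attainable with the printed arrival rates). Department-level elective
demand is split proportionally to bookable capacity, so each department's
program fills at a comparable rate.

**Duration-class mix.** Generated electives are short/medium/long with
probabilities 0.62/0.27/0.11. This is the package's own calibration choice
- class means are conditional means of a clustered, right-skewed empirical
distribution, in which short cases dominate counts. The mix was set so
that (a) the planned weekly elective load slightly exceeds bookable
regular-hours capacity (about 105%), which keeps schedules full, makes
policy comparisons capacity-limited, and reproduces the observed
behaviour that weekly throughput responds to scheduling policy; and (b)
the three published output anchors (Base-Case emergency waiting ≈ 4.5 min,
closed-emergency-room waiting ≈ 22.7 min, ≈ 10% extra throughput under
parallel induction with one extra team) are jointly reproduced. The
`classify_duration_class()` utility uses tercile thresholds of the
per-specialty presence distribution, the natural forecast classifier; the
generation mix is deliberately a separate knob.

## Scheduling

Each department fills its rooms the evening before execution from a
three-tier waiting list: semi-urgent patients first, then previously
deferred cases in their original order, then electives FIFO. A patient is
placed into the least-loaded room of the department where its planned slot
still fits inside the 435-minute regular window (08:30-15:45); patients
that do not fit stay on the list, but shorter cases behind them may still
be booked. Planned slots are the expected presence time plus expected
cleaning; under parallel induction they shrink to expected occupation plus
cleaning, which is what lets additional patients fit - this tightening is
applied in *all* parallel scenarios, including zero extra teams, which is
exactly why deferrals spike there. The sequencing policy (FIFO/SF/LF)
reorders each finished room schedule without changing its patient set, and
planned starts are recomputed back-to-back from 08:30.

## Execution engine

The intraday core is an event-driven simulator (compiled C++ under `src/`,
as is usual for discrete-event cores in R packages). All sampling happens
in R before execution; the executor is deterministic given its inputs,
which makes common-random-number comparisons and the degenerate
(dispersion-zero) checks exact.

Key operational rules, each of which matters for at least one published
effect:

* **Serial chain (Base Case).** Induction, occupation and cleaning of a
  case block the room back-to-back; the next induction starts when the
  room is clean. Expected cycle time equals the planned slot.
* **Parallel induction.** When a patient enters the room, the next
  patient's induction is requested from the team pool (extra teams, plus
  the emergency-room team whenever that room is idle with no inbound
  emergency). If a team is free, the induction runs in an induction room
  (at most 13 concurrently) and the OR is re-occupied the moment cleaning
  ends; if no team became available by then, the case degrades to the
  serial chain. The first patient of a session is never overlapped.
* **Staffing model.** A room whose day program has finished releases its
  staff and closes; it does not linger as emergency stand-by. Buffered
  rooms are deliberately staffed until the extended close; the dedicated
  emergency room around the clock; night rooms during the night shift and
  around the clock on weekends (the weekend emergency service). This
  staffing model is load-bearing: it creates the evening coverage gap that
  makes closing the dedicated emergency room expensive (waits of tens of
  minutes) and extended hours valuable for urgent patients.
* **Break-in routing.** Room selection happens at notice time using
  projected availability (current case end plus cleaning, plus break-ins
  already queued ahead); the chosen room's pending patients are postponed,
  and any of them whose projected start now falls past the effective close
  is deferred to the next day. Emergencies prefer the dedicated room when
  free and may queue at it; very-urgent routing is deadline-aware as
  described above. Break-ins are never deferred.
* **End-of-day rules.** Before the regular close, a ready case always
  starts (possibly running into overtime - started cases are never
  abandoned). From the close onwards, a pending case starts only if its
  projected end fits inside the effective close (regular close plus buffer
  hours); in buffer scenarios a pending case may migrate to another
  staffed room that can finish it in time; everything else is deferred to
  the next day's program, ahead of newly booked electives.
* **Waiting times.** For scheduled patients, waiting is the delay between
  the frozen planned start and actual room entry, clipped at zero; a
  deferral resets the reference to the next day's plan. For break-ins the
  reference is the ready-for-surgery time. By default `notice_lead = 0`:
  the coordinator's ~30-minute advance notice is treated as a real-world
  mitigation outside the model, which is the reading consistent with the
  published waiting levels (modeled pre-allocation would clip almost all
  emergency waits to zero given 17 candidate rooms).

## Performance indicators and experiment design

`compute_kpis()` reports treated cases and deferral events per week,
waiting times per acuity, room utilization (surgery + cleaning) and system
utilization (+ anesthesia) in the regular (08:30-15:45) and extended
(15:45-20:00) windows, overtime/undertime per elective room-day against
the 15:45 close, and the anesthesia turnover time, operationalized as the
mean gap between a patient's room exit and the next patient's procedure
start (the quantity parallel induction compresses; it has no standard
definition). The dedicated emergency room is excluded from the elective
utilization and overtime aggregates.

Scenario experiments run independent replications with seeds `base_seed +
replication index`; all scenarios reuse the same seeds, and the demand
stream depends only on the calibration and seed - never on the policy - so
per-replication differences are pure policy effects (common random
numbers). Aggregation uses two-sided 95% t-intervals; two scenarios whose
intervals do not overlap differ significantly at the 0.05 level, and
`contrast_ci()` provides the sharper paired version.

**Problem sizes.** The package defaults are 30 replications of 52
post-warm-up weeks with a 4-week warm-up, the sizes used by
`scripts/acceptance.R`. The test suite exercises the same directional
contrasts at 30 replications of 10 post-warm-up weeks, which paired
contrasts comfortably resolve. Warm-up exists to let the elective waiting
list reach its working level: the default calibration is deliberately
slightly over-subscribed, so early weeks with an empty list are not
representative.

## Numerical choices and degenerate inputs

Log-normal components are parameterized by mean and CV
(`sdlog = sqrt(log(1 + cv^2))`); CV = 0 degenerates to the exact mean, and
with all dispersions zero and arrivals silenced the realized timeline
equals the frozen plan minute for minute (a test asserts this). Sequencing
ties break by original FIFO position. The projected-overrun test at the
close uses planned lengths, strict inequality, at decision time; realized
lengths govern outcomes. Events at equal times resolve in insertion order,
so runs are bit-reproducible for a given seed. Class-tercile thresholds
are computed from the closed-form CDF of the class mixture
(per-class log-normal approximation) by root finding.

## What the generator does and does not emulate

The synthetic model reproduces printed means (arrival rates, presence
times, volumes) and qualitative shape (right skew, cardiac bimodality,
emergency inflation). It does not emulate: seasonal or weekday
heterogeneity beyond the day/night and weekday/weekend split; correlations
between a patient's duration components; no-shows, transport failures or
missing paperwork (which is why a real theatre treats ~5% fewer patients
than an idealized simulation); surgeon-level constraints; or downstream
ICU/ward capacity. Passing tests therefore demonstrate internal
consistency with the calibrated summary statistics, not fidelity to any
patient-level dataset.

## Known limitations

* The presence split into induction and occupation (20/80) is a modeling
  default, not an observed decomposition; the parallel-induction gain
  scales with it.
* Sequential-mode turnover times are structurally longer than published
  practice values because in-room induction is charged to the gap.
* Deferred patients keep a completed pre-induction out of the books; the
  wasted team time is not reported.
* Buffer-room migration assumes the receiving room's team can host any
  department's case.
* The sub-minute ordering of emergency waiting times across sequencing
  policies is sensitive to engine details. Here shortest-first's larger
  overtime keeps rooms staffed later into the evening - when break-in
  capacity is scarcest - giving SF a slight edge over FIFO; reports from
  practice instead tend to favour FIFO via break-in-moment density. The
  corresponding check in the test suite documents this discrepancy and
  fails by design.
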