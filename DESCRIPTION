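Package: orsim
Type: Package
Title: Discrete-Event Simulation of Operating Theatre Management Policies
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-event simulation of a large multi-department operating
    theatre (18 operating rooms, a dedicated emergency room, two night rooms,
    and a shared pool of anesthesia induction rooms). Generates synthetic
    patient streams (elective, semi-urgent, very-urgent and emergency cases)
    calibrated to published arrival rates and anesthesia presence times,
    executes department day schedules against stochastic surgery durations,
    and evaluates management policies - end-of-day buffer hours, parallel
    induction of anesthesia with a bounded team pool, elective sequencing
    (FIFO, shortest-first, longest-first) and closing the dedicated emergency
    room - against a Base Case on standard theatre performance indicators
    (treated cases, deferrals, utilization, overtime/undertime, waiting times)
    with replication-based 95% confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
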