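# Independent brute-force oracle for small deterministic day instances:
# replays the stated rule set (serial in-room chain per room, strict
# projected-overrun deferral at the regular close) with plain arithmetic,
# without touching the event engine.

oracle_single_room_day <- function(induction, occupation, cleaning,
                                   planned_len,
                                   reg_open = 510, reg_close = 945,
                                   eff_close = 945) {
  n <- length(induction)
  out <- data.frame(enter = rep(NA_real_, n), proc = NA_real_,
                    exit = NA_real_, clean = NA_real_,
                    deferred = rep(FALSE, n))
  t <- reg_open
  for (i in seq_len(n)) {
    s <- max(t, reg_open)
    if (s >= reg_close && s + planned_len[i] > eff_close) {
      out$deferred[i] <- TRUE
      next
    }
    out$enter[i] <- s
    out$proc[i] <- s + induction[i]
    out$exit[i] <- out$proc[i] + occupation[i]
    out$clean[i] <- out$exit[i] + cleaning[i]
    t <- out$clean[i]
  }
  out
}
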