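# Brute-force oracles, written directly from the verbal definitions and kept
# independent of the package's implementations.

# Maximal runs of TRUE in a binary vector, by a plain day-by-day scan.
oracle_attacks <- function(m) {
  runs <- integer(0)
  cur <- 0L
  for (t in seq_along(m)) {
    if (m[t]) cur <- cur + 1L
    else if (cur > 0L) { runs <- c(runs, cur); cur <- 0L }
  }
  if (cur > 0L) runs <- c(runs, cur)
  runs
}

# Locked days: free days with a recorded migraine day on both sides.
oracle_locked <- function(m) {
  which(vapply(seq_along(m), function(t) {
    t > 1L && t < length(m) && !m[t] && m[t - 1L] && m[t + 1L]
  }, logical(1)))
}

# Start-of-day state of each day, computed by looking backward from scratch
# at every day (no carried state).
oracle_states <- function(m, quarantine) {
  vapply(seq_along(m), function(t) {
    if (t == 1L) return("W")
    k <- 0L
    while (t - 1L - k >= 1L && m[t - 1L - k]) k <- k + 1L
    if (k > 0L) return(as.character(k))
    if (quarantine && t >= 3L && !m[t - 1L] && m[t - 2L]) return("Q")
    "W"
  }, character(1))
}

oracle_events <- function(m, states) {
  vapply(seq_along(m), function(t) {
    s <- states[t]
    if (s == "Q") "quarantine_exit"
    else if (s == "W") { if (m[t]) "onset" else "stay_W" }
    else if (m[t]) "continue" else "terminate"
  }, character(1))
}

# Omnibus continuation counts straight from the record: days whose
# predecessor is a migraine day are at risk of continuing.
oracle_omnibus <- function(m) {
  at_risk <- which(seq_along(m) > 1L & c(FALSE, m[-length(m)]))
  c(x = sum(m[at_risk]), n = length(at_risk))
}

# All binary vectors of a given length, as rows.
all_binary <- function(len) {
  m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), len))) == TRUE
  dimnames(m) <- NULL
  m
}

random_diary <- function(len, p = 0.3, id = "r") {
  diary(id, stats::runif(len) < p)
}

# Hand-built transition counts for edge-case tests.
new_counts_for_test <- function(onset_x, onset_n, cont_x, cont_n, q_days = 0L) {
  structure(list(onset_x = onset_x, onset_n = onset_n,
                 cont_x = cont_x, cont_n = cont_n, q_days = q_days),
            class = "transition_counts")
}
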