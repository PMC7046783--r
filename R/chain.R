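#' Map diary days to Markov-chain states
#'
#' Each day of the diary is assigned the chain state occupied at the
#' \emph{start} of that day, i.e. the state determined by the record up to
#' the previous day:
#' \itemize{
#'   \item the first diary day starts in the well state `W` (nothing is
#'     known before the record, so a migraine on day one counts as an onset);
#'   \item if the previous day was the k-th consecutive migraine day, the day
#'     starts in attack state `k`;
#'   \item with `quarantine = TRUE`, if the previous day was the first
#'     migraine-free day after a migraine day, the day starts in the
#'     quarantine state `Q` (no new onset can be declared during it);
#'   \item otherwise the day starts in `W`.
#' }
#' The day's own record then determines the transition event realised during
#' it: from `W`, a migraine day is an `onset` and a free day a `stay_W`; from
#' attack state `k`, a migraine day is a `continue` and a free day a
#' `terminate`; from `Q` the exit back to `W` is deterministic
#' (`quarantine_exit`). With `quarantine = FALSE` the day after an attack's
#' first free day maps directly to `W`.
#'
#' With quarantine enabled the diary must contain no migraine-locked days
#' (apply [fill48()] first): a locked day would be a migraine day inside the
#' quarantine state, where the model declares onsets impossible.
#'
#' @param d A `diary`.
#' @param quarantine Logical; include the post-attack quarantine state.
#'   Use `TRUE` for Fill48-processed diaries, `FALSE` for raw diaries.
#' @return A data frame of class `"state_sequence"` with columns `day`,
#'   `state` (`"W"`, `"Q"` or the attack-day index as a string) and `event`
#'   (`stay_W`, `onset`, `continue`, `terminate`, `quarantine_exit`);
#'   attributes `diary_id` and `quarantine`.
#' @export
#' @examples
#' map_states(fill48(worked_example()), quarantine = TRUE)
map_states <- function(d, quarantine = TRUE) {
  stopifnot(inherits(d, "diary"))
  if (quarantine && length(find_locked_days(d)) > 0L)
    stop("diary '", d$patient_id, "' contains migraine-locked days; ",
         "apply fill48() before mapping with quarantine = TRUE")
  m <- d$migraine
  n <- length(m)
  state <- character(n)
  event <- character(n)
  run <- 0L       # consecutive migraine days ending at the previous day
  post <- FALSE   # previous day was the first free day after an attack
  for (t in seq_len(n)) {
    state[t] <- if (t == 1L) "W"
                else if (run > 0L) as.character(run)
                else if (quarantine && post) "Q"
                else "W"
    event[t] <- if (state[t] == "Q") "quarantine_exit"
                else if (state[t] == "W") { if (m[t]) "onset" else "stay_W" }
                else if (m[t]) "continue" else "terminate"
    post <- run > 0L && !m[t]
    run <- if (m[t]) run + 1L else 0L
  }
  structure(data.frame(day = diary_days(d), state = state, event = event),
            class = c("state_sequence", "data.frame"),
            diary_id = d$patient_id, quarantine = quarantine)
}

#' Tally transition events from a state sequence
#'
#' Every day contributes exactly one event to exactly one tally: days in `W`
#' to the onset denominator (onsets to its numerator), days in attack state
#' `i` to the continuation denominator for `i` (continues to its numerator),
#' and days in `Q` to the quarantine-day count.
#'
#' @param ss A `state_sequence` from [map_states()].
#' @return A list of class `"transition_counts"`: `onset_x`, `onset_n`,
#'   `cont_x` and `cont_n` (vectors indexed by attack-day `i`), and `q_days`.
#' @export
#' @examples
#' tally_transitions(map_states(fill48(worked_example())))  # onsets 2/3
tally_transitions <- function(ss) {
  stopifnot(inherits(ss, "state_sequence"))
  is_i <- !ss$state %in% c("W", "Q")
  imax <- if (any(is_i)) max(as.integer(ss$state[is_i])) else 0L
  cont_x <- cont_n <- integer(imax)
  if (imax > 0L) {
    i <- as.integer(ss$state[is_i])
    cont_n <- as.integer(tabulate(i, imax))
    cont_x <- as.integer(tabulate(i[ss$event[is_i] == "continue"], imax))
  }
  new_transition_counts(
    onset_x = sum(ss$event == "onset"),
    onset_n = sum(ss$state == "W"),
    cont_x = cont_x, cont_n = cont_n,
    q_days = sum(ss$state == "Q"))
}

new_transition_counts <- function(onset_x, onset_n, cont_x, cont_n, q_days) {
  stopifnot(onset_x <= onset_n, all(cont_x <= cont_n),
            onset_n >= 0L, all(cont_n >= 0L))
  structure(list(onset_x = as.integer(onset_x), onset_n = as.integer(onset_n),
                 cont_x = as.integer(cont_x), cont_n = as.integer(cont_n),
                 q_days = as.integer(q_days)),
            class = "transition_counts")
}

#' @export
print.transition_counts <- function(x, ...) {
  cat(sprintf("Transition counts: onsets %d/%d; quarantine days %d\n",
              x$onset_x, x$onset_n, x$q_days))
  if (length(x$cont_n))
    cat(" continuations by attack day i:",
        paste(sprintf("%d:%d/%d", seq_along(x$cont_n), x$cont_x, x$cont_n),
              collapse = " "), "\n")
  invisible(x)
}

#' Pool transition counts over diaries
#'
#' Element-wise sums; the longest attack observed in any diary sets the
#' truncation bound `n` (the length of the pooled continuation vectors).
#'
#' @param counts A list of `transition_counts`.
#' @return A single pooled `transition_counts`.
#' @export
pool_counts <- function(counts) {
  if (inherits(counts, "transition_counts")) counts <- list(counts)
  stopifnot(length(counts) >= 1L,
            all(vapply(counts, inherits, logical(1), "transition_counts")))
  imax <- max(vapply(counts, function(cc) length(cc$cont_n), integer(1)))
  pad <- function(v) c(v, integer(imax - length(v)))
  new_transition_counts(
    onset_x = sum(vapply(counts, `[[`, integer(1), "onset_x")),
    onset_n = sum(vapply(counts, `[[`, integer(1), "onset_n")),
    cont_x = Reduce(`+`, lapply(counts, function(cc) pad(cc$cont_x))),
    cont_n = Reduce(`+`, lapply(counts, function(cc) pad(cc$cont_n))),
    q_days = sum(vapply(counts, `[[`, integer(1), "q_days")))
}

#' Pooled transition counts for a cohort
#'
#' Convenience wrapper running the full tallying pipeline: optional Fill48
#' imputation, state mapping (quarantine enabled in `"fill48"` mode,
#' disabled in `"raw"` mode unless overridden), tallying, and pooling.
#'
#' @param x A `cohort`.
#' @param mode `"fill48"` or `"raw"`.
#' @param quarantine Override the mode's default quarantine setting.
#' @return A pooled `transition_counts`.
#' @export
#' @examples
#' cohort_transition_counts(cohort(worked_example()), mode = "fill48")
cohort_transition_counts <- function(x, mode = c("fill48", "raw"),
                                     quarantine = NULL) {
  stopifnot(inherits(x, "cohort"), length(x) >= 1L)
  mode <- match.arg(mode)
  if (is.null(quarantine)) quarantine <- mode == "fill48"
  if (mode == "fill48") x <- fill48(x)
  pool_counts(lapply(x, function(d)
    tally_transitions(map_states(d, quarantine = quarantine))))
}
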