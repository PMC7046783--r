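#' Find migraine-locked days
#'
#' A migraine-locked day is a migraine-free diary day whose immediately
#' preceding and immediately succeeding days are both migraine days. The
#' first and last days of a diary are never locked: one of their neighbours
#' is unobserved, and the definition requires both neighbours on record.
#'
#' @param d A `diary`.
#' @return Integer vector of locked day numbers (possibly empty).
#' @seealso [fill48()]
#' @export
#' @examples
#' find_locked_days(worked_example())  # day 31
find_locked_days <- function(d) {
  stopifnot(inherits(d, "diary"))
  m <- d$migraine
  n <- length(m)
  if (n < 3L) return(integer(0))
  mid <- 2:(n - 1L)
  locked <- !m[mid] & m[mid - 1L] & m[mid + 1L]
  diary_days(d)[mid][locked]
}

#' Fill48 imputation of migraine-locked days
#'
#' Imputes every migraine-locked day of the input as a migraine day, marking
#' it with the `imputed` flag. Detection is simultaneous on the input record:
#' all locked days are found first, then flipped in one pass. (Imputation can
#' never create a new locked day, so sequential re-scanning would give the
#' same result; the single pass makes the definition deterministic.) Each
#' imputed day merges the two attacks flanking it into one longer attack.
#'
#' The name reflects the clinical convention that headache returning within
#' roughly 48 hours of relief is a relapse of the same attack, not a new one;
#' no hour-level arithmetic is involved, only the day-level pattern.
#'
#' @param x A `diary` or a `cohort`.
#' @return An object of the same class with locked days imputed. Idempotent:
#'   `fill48(fill48(x))` equals `fill48(x)`.
#' @export
#' @examples
#' fill48(worked_example())  # 5 migraine days in 2 attacks
fill48 <- function(x) UseMethod("fill48")

#' @export
fill48.diary <- function(x) {
  locked <- find_locked_days(x)
  if (length(locked) == 0L) return(x)
  idx <- match(locked, diary_days(x))
  x$migraine[idx] <- TRUE
  x$imputed[idx] <- TRUE
  x
}

#' @export
fill48.cohort <- function(x) {
  structure(lapply(x, fill48), class = "cohort")
}
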