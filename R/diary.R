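#' Construct a daily headache diary
#'
#' A diary is an ordered record of consecutive days for one patient, each day
#' flagged as a migraine day or a migraine-free day. Day numbers are 1-based,
#' contiguous, and need not start at 1 (a diary excerpt may start mid-record).
#'
#' @param patient_id Character scalar identifying the patient.
#' @param migraine Logical (or 0/1) vector, one element per day, `TRUE` on
#'   migraine days.
#' @param first_day Integer day number of the first record (default 1).
#' @param imputed Logical vector marking days whose migraine flag was set by
#'   Fill48 imputation rather than recorded by the patient. Defaults to all
#'   `FALSE`. An imputed day must be a migraine day.
#' @param age_years Optional non-negative number; descriptive metadata only.
#' @param sex Optional character code; descriptive metadata only.
#'
#' @return An object of class `"diary"`.
#' @seealso [read_diaries()], [worked_example()], [fill48()]
#' @export
#' @examples
#' d <- diary("p1", c(0, 1, 0, 1))
#' diary_days(d)
diary <- function(patient_id, migraine, first_day = 1L, imputed = NULL,
                  age_years = NULL, sex = NULL) {
  if (!is.character(patient_id) || length(patient_id) != 1L || is.na(patient_id))
    stop("'patient_id' must be a single non-missing string")
  migraine <- as_binary_flag(migraine, "migraine")
  if (length(migraine) < 1L)
    stop("a diary must contain at least one day")
  first_day <- as.integer(first_day)
  if (length(first_day) != 1L || is.na(first_day))
    stop("'first_day' must be a single integer")
  if (is.null(imputed)) imputed <- rep(FALSE, length(migraine))
  imputed <- as_binary_flag(imputed, "imputed")
  if (length(imputed) != length(migraine))
    stop("'imputed' must have one flag per day")
  if (any(imputed & !migraine))
    stop("an imputed day must be a migraine day")
  if (!is.null(age_years)) {
    age_years <- as.numeric(age_years)
    if (length(age_years) != 1L || (!is.na(age_years) && age_years < 0))
      stop("'age_years' must be a single non-negative number")
  }
  structure(
    list(patient_id = patient_id, first_day = first_day,
         migraine = migraine, imputed = imputed,
         age_years = age_years, sex = sex),
    class = "diary")
}

as_binary_flag <- function(x, what) {
  if (is.logical(x)) {
    if (anyNA(x)) stop("'", what, "' flags must not be missing")
    return(x)
  }
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x) || !all(x %in% c(0, 1)))
    stop("'", what, "' flags must be binary (0/1)")
  x == 1
}

#' Day numbers covered by a diary
#' @param d A `diary`.
#' @return Integer vector of contiguous day numbers.
#' @export
diary_days <- function(d) {
  stopifnot(inherits(d, "diary"))
  seq.int(d$first_day, length.out = length(d$migraine))
}

#' Number of observed days in a diary
#' @param d A `diary`.
#' @export
n_days <- function(d) {
  stopifnot(inherits(d, "diary"))
  length(d$migraine)
}

#' @export
print.diary <- function(x, ...) {
  cat(sprintf("Headache diary '%s': days %d-%d (%d days, %d migraine days)\n",
              x$patient_id, x$first_day, x$first_day + length(x$migraine) - 1L,
              length(x$migraine), sum(x$migraine)))
  cat(" ", diary_symbols(x), "\n", sep = "")
  invisible(x)
}

# Symbol encoding: 'M' = migraine day, '-' = migraine-free day.
diary_symbols <- function(d) {
  paste(ifelse(d$migraine, "M", "-"), collapse = "")
}

#' Construct a cohort of diaries
#'
#' @param ... `diary` objects, or a single list of them.
#' @return An object of class `"cohort"`: an ordered list of diaries with
#'   unique patient ids.
#' @export
#' @examples
#' co <- cohort(diary("p1", c(1, 0)), diary("p2", c(0, 1)))
#' length(co)
cohort <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1L]], "diary")) ds <- ds[[1L]]
  if (!all(vapply(ds, inherits, logical(1), what = "diary")))
    stop("all elements of a cohort must be 'diary' objects")
  ids <- vapply(ds, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop("duplicate patient_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(stats::setNames(ds, ids), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nd <- vapply(x, n_days, integer(1))
  cat(sprintf("Cohort of %d headache diaries (%d diary days, %d migraine days)\n",
              length(x), sum(nd),
              sum(vapply(x, function(d) sum(d$migraine), integer(1)))))
  invisible(x)
}

#' @export
`[.cohort` <- function(x, i) {
  structure(NextMethod(), class = "cohort")
}

#' The in-package worked-example diary
#'
#' A 9-day hypothetical diary excerpt covering days 29 to 37, with migraine
#' recorded on days 30, 32, 35 and 36. It contains 4 migraine days in 3
#' attacks (onsets on days 30, 32 and 35); day 31 is a migraine-locked day,
#' so Fill48 imputation merges the first two attacks, giving 5 migraine days
#' in 2 attacks.
#'
#' @return A `diary`.
#' @export
#' @examples
#' worked_example()
#' find_locked_days(worked_example())
worked_example <- function() {
  diary("example", first_day = 29L,
        migraine = c(0, 1, 0, 1, 0, 0, 1, 1, 0))
}

#' Read headache diaries from a file
#'
#' Two plain-text layouts are supported:
#' \describe{
#'   \item{`"long"`}{Delimited table with header
#'     `patient_id,day,migraine[,imputed]`, one row per patient-day.}
#'   \item{`"symbol"`}{One line per patient, `<patient_id>: <string>` where
#'     the string is over `M` (migraine day) and `-` (free day); the first
#'     day number is `first_day` for every patient.}
#' }
#'
#' Day numbers within a patient must be contiguous. A gap is an error unless
#' `split_at_gaps = TRUE`, in which case the patient's record is split at
#' each gap into independent sub-diaries with ids suffixed `.1`, `.2`, ...
#'
#' @param path Path to the input file.
#' @param format `"long"` or `"symbol"`.
#' @param split_at_gaps Split long-format diaries at day-number gaps instead
#'   of erroring.
#' @param first_day First day number assigned in symbol format (default 1).
#' @return A `cohort`.
#' @seealso [write_diaries()]
#' @export
read_diaries <- function(path, format = c("long", "symbol"),
                         split_at_gaps = FALSE, first_day = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "symbol") read_diaries_symbol(path, first_day)
  else read_diaries_long(path, split_at_gaps)
}

read_diaries_symbol <- function(path, first_day) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  ds <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[i], regexec("^\\s*([^:]+?)\\s*:\\s*([M-]+)\\s*$", lines[i]))[[1L]]
    if (length(m) != 3L)
      stop("parse error at line ", i, ": expected '<patient_id>: <string over {M,-}>', got: ",
           lines[i])
    ds[[i]] <- diary(m[2L], strsplit(m[3L], "")[[1L]] == "M",
                     first_day = first_day)
  }
  cohort(ds)
}

read_diaries_long <- function(path, split_at_gaps) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  header <- strsplit(trimws(lines[1L]), ",")[[1L]]
  need <- c("patient_id", "day", "migraine")
  if (!identical(header[seq_along(need)], need) ||
      !(length(header) == 3L || identical(header[4L], "imputed")) ||
      length(header) > 4L)
    stop("parse error at line 1: expected header 'patient_id,day,migraine[,imputed]'")
  has_imp <- length(header) == 4L
  n <- length(lines) - 1L
  pid <- character(n); day <- integer(n); mig <- integer(n); imp <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], ",")[[1L]]
    if (length(f) != length(header))
      stop("parse error at line ", i + 1L, ": expected ", length(header),
           " fields, got ", length(f))
    d <- suppressWarnings(as.integer(f[2L]))
    v <- suppressWarnings(as.integer(f[3L]))
    if (is.na(d)) stop("parse error at line ", i + 1L, ": non-integer day '", f[2L], "'")
    if (is.na(v) || !v %in% 0:1)
      stop("parse error at line ", i + 1L, ": migraine flag must be 0 or 1, got '", f[3L], "'")
    pid[i] <- trimws(f[1L]); day[i] <- d; mig[i] <- v
    if (has_imp) {
      w <- suppressWarnings(as.integer(f[4L]))
      if (is.na(w) || !w %in% 0:1)
        stop("parse error at line ", i + 1L, ": imputed flag must be 0 or 1, got '", f[4L], "'")
      imp[i] <- w
    }
  }
  if (n == 0L) return(cohort(list()))
  ds <- list()
  for (id in unique(pid)) {
    sel <- pid == id
    o <- order(day[sel])
    dd <- day[sel][o]; mm <- mig[sel][o]; ii <- imp[sel][o]
    if (anyDuplicated(dd))
      stop("validation error: duplicate (patient, day) record for patient '",
           id, "', day ", dd[which(duplicated(dd))[1L]])
    gaps <- which(diff(dd) != 1L)
    if (length(gaps) && !split_at_gaps)
      stop("validation error: day ", dd[gaps[1L]] + 1L,
           " missing for patient '", id,
           "' (use split_at_gaps to split at gaps)")
    starts <- c(1L, gaps + 1L)
    ends <- c(gaps, length(dd))
    for (k in seq_along(starts)) {
      sid <- if (length(starts) == 1L) id else paste0(id, ".", k)
      idx <- starts[k]:ends[k]
      ds[[length(ds) + 1L]] <- diary(sid, mm[idx], first_day = dd[starts[k]],
                                     imputed = ii[idx] == 1L)
    }
  }
  cohort(ds)
}

#' Write headache diaries to a file
#'
#' Inverse of [read_diaries()]. Long format always includes the `imputed`
#' column, so Fill48 provenance survives a round trip; symbol format records
#' only the migraine flags (pass the matching `first_day` when re-reading
#' diaries that do not start at day 1).
#'
#' @param x A `cohort` (or a single `diary`).
#' @param path Output path.
#' @param format `"long"` or `"symbol"`.
#' @return `path`, invisibly.
#' @export
write_diaries <- function(x, path, format = c("long", "symbol")) {
  format <- match.arg(format)
  if (inherits(x, "diary")) x <- cohort(x)
  stopifnot(inherits(x, "cohort"))
  if (format == "symbol") {
    lines <- vapply(x, function(d) paste0(d$patient_id, ": ", diary_symbols(d)),
                    character(1))
  } else {
    lines <- "patient_id,day,migraine,imputed"
    for (d in x) {
      lines <- c(lines, sprintf("%s,%d,%d,%d", d$patient_id, diary_days(d),
                                as.integer(d$migraine), as.integer(d$imputed)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
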