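#' Segment a diary into discrete migraine attacks
#'
#' An attack is a maximal run of consecutive migraine days; the first
#' migraine-free day after the run ends it. Runs touching a diary boundary
#' are flagged as censored (their true duration is only partially observed).
#'
#' @param d A `diary`.
#' @return A data frame of class `"attack_table"` with one row per attack:
#'   `start_day`, `duration`, `left_censored`, `right_censored`. The diary id
#'   is kept in attribute `"diary_id"`.
#' @export
#' @examples
#' segment_attacks(worked_example())          # 3 attacks: 1, 1, 2 days
#' segment_attacks(fill48(worked_example()))  # 2 attacks: 3, 2 days
segment_attacks <- function(d) {
  stopifnot(inherits(d, "diary"))
  r <- rle(d$migraine)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  att <- data.frame(
    start_day = diary_days(d)[starts[keep]],
    duration = r$lengths[keep],
    left_censored = starts[keep] == 1L,
    right_censored = ends[keep] == length(d$migraine))
  structure(att, class = c("attack_table", "data.frame"),
            diary_id = d$patient_id)
}

#' Per-diary descriptive statistics
#'
#' @param d A `diary`.
#' @param exclude_censored Drop attacks that touch a diary boundary from the
#'   attack count and duration statistics (sensitivity analysis; by default
#'   censored attacks are kept at their observed duration).
#' @return A list of class `"diary_summary"`: `observed_days`,
#'   `migraine_days`, `attack_count`, `locked_days` (counted on the record as
#'   given, before any imputation you may apply), `migraine_days_per30`,
#'   `locked_days_per30`, and `durations` (one entry per attack).
#' @export
summarise_diary <- function(d, exclude_censored = FALSE) {
  stopifnot(inherits(d, "diary"))
  att <- segment_attacks(d)
  if (exclude_censored)
    att <- att[!att$left_censored & !att$right_censored, , drop = FALSE]
  nd <- n_days(d)
  locked <- length(find_locked_days(d))
  structure(list(
    patient_id = d$patient_id,
    observed_days = nd,
    migraine_days = sum(d$migraine),
    attack_count = nrow(att),
    locked_days = locked,
    migraine_days_per30 = 30 * sum(d$migraine) / nd,
    locked_days_per30 = 30 * locked / nd,
    durations = att$duration), class = "diary_summary")
}

#' @export
print.diary_summary <- function(x, ...) {
  cat(sprintf(
    "Diary '%s': %d days, %d migraine days (%.1f per 30), %d attacks, %d locked days\n",
    x$patient_id, x$observed_days, x$migraine_days, x$migraine_days_per30,
    x$attack_count, x$locked_days))
  invisible(x)
}

resolve_mode <- function(x, mode = c("raw", "fill48")) {
  mode <- match.arg(mode)
  if (mode == "fill48") fill48(x) else x
}

#' Cohort-level descriptive statistics
#'
#' Per-diary statistics (migraine days, attacks, migraine days per 30
#' observed days, locked days per 30) are aggregated as median, 25th/75th
#' percentiles and mean across diaries. Attack durations are pooled over all
#' attacks of all diaries, so the mean duration equals total migraine days
#' divided by total attacks. Percentiles use linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param x A `cohort`.
#' @param mode `"raw"` analyses the diaries as given; `"fill48"` applies
#'   locked-day imputation first.
#' @param exclude_censored Passed to [summarise_diary()].
#' @return A data frame with one row per statistic and columns
#'   `statistic`, `median`, `q25`, `q75`, `mean`.
#' @export
cohort_summary <- function(x, mode = c("raw", "fill48"),
                           exclude_censored = FALSE) {
  stopifnot(inherits(x, "cohort"))
  if (length(x) == 0L) stop("empty cohort")
  mode <- match.arg(mode)
  raw_locked <- vapply(x, function(d) length(find_locked_days(d)), integer(1))
  raw_locked_per30 <- 30 * raw_locked / vapply(x, n_days, integer(1))
  x <- resolve_mode(x, mode)
  ss <- lapply(x, summarise_diary, exclude_censored = exclude_censored)
  num <- function(f) vapply(ss, `[[`, numeric(1), f)
  durations <- unlist(lapply(ss, `[[`, "durations"), use.names = FALSE)
  row <- function(v) c(median = stats::median(v),
                       q25 = unname(stats::quantile(v, 0.25)),
                       q75 = unname(stats::quantile(v, 0.75)),
                       mean = mean(v))
  stats_tab <- rbind(
    observed_days = row(num("observed_days")),
    migraine_days = row(num("migraine_days")),
    migraine_attacks = row(num("attack_count")),
    migraine_days_per30 = row(num("migraine_days_per30")),
    locked_days_per30 = row(raw_locked_per30),
    attack_duration = if (length(durations))
      c(row(durations)[1:3], mean = sum(num("migraine_days")) / sum(num("attack_count")))
    else c(median = NA, q25 = NA, q75 = NA, mean = NA))
  out <- data.frame(statistic = rownames(stats_tab), stats_tab,
                    row.names = NULL, check.names = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Attack-duration histogram
#'
#' @param x A `cohort`.
#' @param mode `"raw"` or `"fill48"` (imputation applied first).
#' @return A data frame with columns `duration` (days) and `count` (number of
#'   attacks of that duration, over all diaries); counts sum to the total
#'   number of attacks.
#' @export
#' @examples
#' duration_histogram(cohort(worked_example()), mode = "raw")
duration_histogram <- function(x, mode = c("raw", "fill48")) {
  stopifnot(inherits(x, "cohort"))
  if (length(x) == 0L) stop("empty cohort")
  x <- resolve_mode(x, match.arg(mode))
  durations <- unlist(lapply(x, function(d) segment_attacks(d)$duration),
                      use.names = FALSE)
  tab <- table(factor(durations, levels = seq_len(max(durations, 1L))))
  data.frame(duration = as.integer(names(tab)), count = as.integer(tab))
}
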