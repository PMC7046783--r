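#' Continuity-corrected Wilson score interval
#'
#' The score interval for a binomial proportion with continuity correction
#' (Newcombe's recommended single-proportion interval). With p = x/n and z
#' the standard-normal quantile at (1 + conf)/2:
#' \deqn{low = \frac{2np + z^2 - 1 - z\sqrt{z^2 - 2 - 1/n + 4p(n(1-p)+1)}}{2(n+z^2)}}
#' \deqn{high = \frac{2np + z^2 + 1 + z\sqrt{z^2 + 2 - 1/n + 4p(n(1-p)-1)}}{2(n+z^2)}}
#' clamped to [0, 1], with low = 0 when x = 0 and high = 1 when x = n. The z
#' quantile is computed exactly, not rounded to 1.96; round only at the
#' reporting stage.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (n >= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
#' @examples
#' round(wilson_cc_interval(3, 3), 3)  # 0.310 1.000
#' round(wilson_cc_interval(0, 3), 3)  # 0.000 0.690
wilson_cc_interval <- function(x, n, conf = 0.95) {
  if (length(x) != 1L || length(n) != 1L || is.na(x) || is.na(n))
    stop("'x' and 'n' must be single numbers")
  if (n < 1) stop("undefined estimate: n must be at least 1")
  if (x < 0 || x > n) stop("'x' must lie in [0, n]")
  if (conf <= 0 || conf >= 1) stop("'conf' must lie in (0, 1)")
  z <- stats::qnorm((1 + conf) / 2)
  p <- x / n
  low <- if (x == 0) 0 else max(0,
    (2 * n * p + z^2 - 1 - z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
      (2 * (n + z^2)))
  high <- if (x == n) 1 else min(1,
    (2 * n * p + z^2 + 1 + z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
      (2 * (n + z^2)))
  c(low = low, high = high)
}

proportion_estimate <- function(label, x, n, conf) {
  ci <- wilson_cc_interval(x, n, conf)
  data.frame(label = label, x = x, n = n, estimate = x / n,
             ci_low = ci[["low"]], ci_high = ci[["high"]], conf = conf)
}

#' Transition-probability point estimates with confidence intervals
#'
#' One row per parameter with a nonzero denominator: the onset probability
#' `mu` (onsets over at-risk well-state days) and each continuation
#' probability `delta_i` (continuations over days in attack state i), with
#' continuity-corrected Wilson score intervals. By construction the last
#' observed `delta` estimate is zero: the longest attack in the data did not
#' continue. Parameters with a zero denominator are skipped with a message.
#'
#' @param counts A `transition_counts`.
#' @param conf Confidence level (default 0.95).
#' @return A data frame of class `"tp_estimates"` with columns `label`, `x`,
#'   `n`, `estimate`, `ci_low`, `ci_high`, `conf`.
#' @export
#' @examples
#' co <- cohort(worked_example())
#' estimate_tps(cohort_transition_counts(co, mode = "fill48"))
estimate_tps <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "transition_counts"))
  rows <- list()
  if (counts$onset_n > 0L)
    rows[[1L]] <- proportion_estimate("mu", counts$onset_x, counts$onset_n, conf)
  else message("skipping mu: no at-risk days observed")
  for (i in seq_along(counts$cont_n)) {
    if (counts$cont_n[i] > 0L)
      rows[[length(rows) + 1L]] <-
        proportion_estimate(paste0("delta_", i), counts$cont_x[i],
                            counts$cont_n[i], conf)
    else message("skipping delta_", i, ": zero denominator")
  }
  if (length(rows) == 0L) stop("undefined estimate: no observations")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("tp_estimates", "data.frame"))
}

#' @export
print.tp_estimates <- function(x, digits = 3, ...) {
  y <- data.frame(TP = x$label, N = x$n,
                  Estimate = round(x$estimate, digits),
                  CI = sprintf("(%.*f, %.*f)", digits, x$ci_low, digits, x$ci_high))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Omnibus continuation probability
#'
#' The probability that an attack continues once begun, without conditioning
#' on how long it has lasted: all attack-day states are collapsed into one,
#' so the numerator is the total continuation count and the denominator the
#' total number of attack-state days.
#'
#' @param counts A `transition_counts`.
#' @param conf Confidence level (default 0.95).
#' @return A one-row `tp_estimates` data frame labelled `delta_omni`.
#' @export
#' @examples
#' co <- cohort(worked_example())
#' estimate_omnibus(cohort_transition_counts(co, mode = "fill48"))  # 3/5
estimate_omnibus <- function(counts, conf = 0.95) {
  stopifnot(inherits(counts, "transition_counts"))
  n <- sum(counts$cont_n)
  if (n < 1L) stop("undefined estimate: no attack-state days observed")
  structure(proportion_estimate("delta_omni", sum(counts$cont_x), n, conf),
            class = c("tp_estimates", "data.frame"))
}

#' Weighted least-squares trend test on continuation probabilities
#'
#' Regresses the estimated continuation probabilities `delta_i` on the attack
#' day `i`, weighting each point by its observation count, and tests the
#' slope against zero (two-sided t test). A flat delta profile supports
#' collapsing the chain to a single duration-unconditional continuation
#' probability.
#'
#' @param tps A `tp_estimates` containing at least three `delta_i` rows.
#' @return A list of class `"trend_test"`: `method`, `slope`, `p_value`, and
#'   the underlying `lm` fit.
#' @export
trend_test_wls <- function(tps) {
  stopifnot(inherits(tps, "tp_estimates"))
  del <- tps[grepl("^delta_[0-9]+$", tps$label), , drop = FALSE]
  if (nrow(del) < 3L)
    stop("need at least 3 delta_i estimates for a trend test")
  del$i <- as.integer(sub("^delta_", "", del$label))
  fit <- stats::lm(estimate ~ i, data = del, weights = del$n)
  co <- suppressWarnings(summary(fit))$coefficients  # degenerate perfect fits
  p <- unname(co["i", "Pr(>|t|)"])
  # a perfectly flat profile carries no evidence of trend; guard against the
  # ~1e-16 residuals it leaves in floating point
  if (diff(range(del$estimate)) < 1e-12) p <- 1
  else if (is.nan(p)) p <- if (abs(co["i", "Estimate"]) < 1e-12) 1 else 0
  structure(list(method = "weighted_ls",
                 slope = unname(co["i", "Estimate"]),
                 p_value = p,
                 fit = fit),
            class = "trend_test")
}

#' Logistic-regression trend test on day-level records
#'
#' Restricts the data to days at risk of continuing an attack (attack states
#' i >= 1) and fits a logistic regression of the day's migraine indicator on
#' the number of preceding consecutive migraine days, either as a linear
#' covariate (default) or as a categorical factor. The Wald p-value for the
#' (first) duration coefficient tests whether continuation depends on how
#' long the attack has lasted. Complete or quasi-complete separation is
#' flagged in the `note` field.
#'
#' @param x A `cohort`.
#' @param mode `"fill48"` (impute, quarantine on) or `"raw"`.
#' @param coding `"linear"` or `"categorical"`.
#' @return A list of class `"trend_test"`: `method`, `coefficient`,
#'   `p_value`, `note`, and the `glm` fit.
#' @export
trend_test_logistic <- function(x, mode = c("fill48", "raw"),
                                coding = c("linear", "categorical")) {
  stopifnot(inherits(x, "cohort"), length(x) >= 1L)
  mode <- match.arg(mode)
  coding <- match.arg(coding)
  quarantine <- mode == "fill48"
  if (mode == "fill48") x <- fill48(x)
  tab <- do.call(rbind, lapply(x, function(d) {
    ss <- map_states(d, quarantine = quarantine)
    at_risk <- !ss$state %in% c("W", "Q")
    if (!any(at_risk)) return(NULL)
    data.frame(patient_id = d$patient_id,
               migraine = as.integer(ss$event[at_risk] == "continue"),
               k = as.integer(ss$state[at_risk]))
  }))
  if (is.null(tab) || length(unique(tab$k)) < 2L)
    stop("no duration contrast: need at-risk days at >= 2 distinct attack days")
  tab$kk <- if (coding == "linear") tab$k else factor(tab$k)
  fit <- withCallingHandlers(
    stats::glm(migraine ~ kk, family = stats::binomial(), data = tab),
    warning = function(w) invokeRestart("muffleWarning"))
  note <- if (!fit$converged || any(abs(fit$coefficients[-1L]) > 10))
    "possible separation: coefficient estimates unreliable" else NA_character_
  co <- summary(fit)$coefficients
  structure(list(method = paste0("logistic_", coding),
                 coefficient = unname(co[2L, "Estimate"]),
                 p_value = unname(co[2L, "Pr(>|z|)"]),
                 note = note, fit = fit),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  eff <- if (!is.null(x$slope)) c("slope", x$slope) else c("coefficient", x$coefficient)
  cat(sprintf("Trend test (%s): %s = %.4g, p = %.4g\n",
              x$method, eff[1L], as.numeric(eff[2L]), x$p_value))
  if (!is.null(x$note) && !is.na(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Individual (per-patient) transition probabilities
#'
#' Estimates each patient's onset probability `mu_j` and omnibus continuation
#' probability `delta_omni_j` from that patient's diary alone, and summarises
#' their spread across the cohort (median and central 95% range of the point
#' estimates). Patients with no at-risk days (or no attack-state days) have
#' the corresponding estimate reported as missing and are excluded from that
#' parameter's summary, with a message giving the count.
#'
#' @param x A `cohort`.
#' @param mode `"fill48"` or `"raw"`.
#' @param conf Confidence level for the per-patient intervals.
#' @return A list of class `"individual_tps"`: `per_patient` (data frame with
#'   `patient_id`, `mu`, `mu_low`, `mu_high`, `delta_omni`, `delta_omni_low`,
#'   `delta_omni_high`) and `summary` (data frame with `parameter`, `median`,
#'   `q2.5`, `q97.5`, `n_defined`).
#' @export
individual_tps <- function(x, mode = c("fill48", "raw"), conf = 0.95) {
  stopifnot(inherits(x, "cohort"), length(x) >= 1L)
  mode <- match.arg(mode)
  quarantine <- mode == "fill48"
  if (mode == "fill48") x <- fill48(x)
  rows <- lapply(x, function(d) {
    cc <- tally_transitions(map_states(d, quarantine = quarantine))
    mu <- if (cc$onset_n > 0L)
      c(cc$onset_x / cc$onset_n, wilson_cc_interval(cc$onset_x, cc$onset_n, conf))
    else rep(NA_real_, 3L)
    nd <- sum(cc$cont_n)
    de <- if (nd > 0L)
      c(sum(cc$cont_x) / nd, wilson_cc_interval(sum(cc$cont_x), nd, conf))
    else rep(NA_real_, 3L)
    data.frame(patient_id = d$patient_id,
               mu = mu[1L], mu_low = mu[2L], mu_high = mu[3L],
               delta_omni = de[1L], delta_omni_low = de[2L],
               delta_omni_high = de[3L])
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  summ <- function(v, nm) {
    miss <- sum(is.na(v))
    if (miss > 0L)
      message(miss, " patient(s) with undefined ", nm, " excluded from summary")
    v <- v[!is.na(v)]
    data.frame(parameter = nm,
               median = stats::median(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               q97.5 = unname(stats::quantile(v, 0.975)),
               n_defined = length(v))
  }
  structure(list(per_patient = per,
                 summary = rbind(summ(per$mu, "mu"),
                                 summ(per$delta_omni, "delta_omni"))),
            class = "individual_tps")
}

#' @export
print.individual_tps <- function(x, ...) {
  cat(sprintf("Individual transition probabilities for %d patients\n",
              nrow(x$per_patient)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Patient-level bootstrap of the pooled transition probabilities
#'
#' Resamples whole diaries with replacement to the original cohort size,
#' re-pools the transition counts, and re-estimates the pooled onset
#' probability and the omnibus continuation probability in each replicate.
#' Reports the percentile interval (2.5th and 97.5th percentiles of the
#' replicate estimates; `stats::quantile` type 7). Per-diary counts are
#' computed once, so each replicate only sums them. Replicates in which an
#' estimate is undefined (zero denominator) are recorded as missing and
#' excluded from that parameter's percentiles, with a message giving the
#' count.
#'
#' @param x A `cohort`.
#' @param B Number of bootstrap replicates (default 1e5).
#' @param seed Integer seed; required, so every run is reproducible.
#' @param mode `"fill48"` or `"raw"`.
#' @param keep_replicates Keep the full replicate vectors in the result.
#' @return A list of class `"bootstrap_tps"`: `B`, `seed`, `mode`, `mu` and
#'   `delta_omni` (each a list with `estimate`, `ci_low`, `ci_high`,
#'   `n_missing`), and optionally `replicates`.
#' @export
bootstrap_tps <- function(x, B = 1e5, seed, mode = c("fill48", "raw"),
                          keep_replicates = FALSE) {
  stopifnot(inherits(x, "cohort"), length(x) >= 1L, B >= 1)
  if (missing(seed)) stop("'seed' is required for a reproducible bootstrap")
  mode <- match.arg(mode)
  quarantine <- mode == "fill48"
  if (mode == "fill48") x <- fill48(x)
  per <- t(vapply(x, function(d) {
    cc <- tally_transitions(map_states(d, quarantine = quarantine))
    c(cc$onset_x, cc$onset_n, sum(cc$cont_x), sum(cc$cont_n))
  }, numeric(4)))
  np <- nrow(per)
  full <- colSums(per)
  mu_b <- numeric(B); de_b <- numeric(B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      s <- colSums(per[sample.int(np, np, replace = TRUE), , drop = FALSE])
      mu_b[b] <- if (s[2L] > 0) s[1L] / s[2L] else NA_real_
      de_b[b] <- if (s[4L] > 0) s[3L] / s[4L] else NA_real_
    }
  })
  pct <- function(v, est, nm) {
    miss <- sum(is.na(v))
    if (miss > 0L)
      message(miss, " replicate(s) with undefined ", nm, " excluded")
    q <- stats::quantile(v, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
    list(estimate = est, ci_low = q[1L], ci_high = q[2L], n_missing = miss)
  }
  out <- list(B = B, seed = seed, mode = mode,
              mu = pct(mu_b, full[1L] / full[2L], "mu"),
              delta_omni = pct(de_b, full[3L] / full[4L], "delta_omni"))
  if (keep_replicates) out$replicates <- data.frame(mu = mu_b, delta_omni = de_b)
  structure(out, class = "bootstrap_tps")
}

#' @export
print.bootstrap_tps <- function(x, ...) {
  cat(sprintf("Patient-level bootstrap (B = %d, seed = %d, mode = %s)\n",
              x$B, x$seed, x$mode))
  for (nm in c("mu", "delta_omni"))
    cat(sprintf("  %-10s %.3f (95%% BS CI %.3f-%.3f)\n", nm,
                x[[nm]]$estimate, x[[nm]]$ci_low, x[[nm]]$ci_high))
  invisible(x)
}
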