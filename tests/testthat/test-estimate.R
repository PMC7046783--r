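test_that("continuity-corrected Wilson interval matches prop.test", {
  # stats::prop.test implements the same continuity-corrected score interval;
  # its correction is clamped by the distance to the null proportion, so pass
  # a null far from x/n to keep the full 1/(2n) correction in force
  for (n in c(1, 2, 3, 5, 10, 40, 165)) {
    for (x in unique(round(c(0, 1, n %/% 3, n %/% 2, n - 1, n)))) {
      if (x < 0 || x > n) next
      p0 <- if (x / n < 0.5) 0.99 else 0.01
      for (conf in c(0.90, 0.95, 0.99)) {
        got <- wilson_cc_interval(x, n, conf)
        ref <- suppressWarnings(
          stats::prop.test(x, n, p = p0, conf.level = conf)$conf.int)
        expect_equal(unname(got), as.numeric(ref), tolerance = 1e-10,
                     label = sprintf("x=%d n=%d conf=%g", x, n, conf))
      }
    }
  }
})

test_that("Wilson interval honours its boundary conventions", {
  expect_identical(wilson_cc_interval(0, 7)[["low"]], 0)
  expect_identical(wilson_cc_interval(7, 7)[["high"]], 1)
  expect_error(wilson_cc_interval(1, 0), "n must be at least 1")
  expect_error(wilson_cc_interval(5, 3), "\\[0, n\\]")
  # the corrected interval contains the uncorrected Wilson score interval
  z <- stats::qnorm(0.975)
  for (x in 0:10) {
    n <- 10
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    cc <- wilson_cc_interval(x, n)
    expect_lte(cc[["low"]], centre - half + 1e-12)
    expect_gte(cc[["high"]], centre + half - 1e-12)
  }
})

test_that("pooled and omnibus estimates reproduce the worked example", {
  cc <- cohort_transition_counts(cohort(worked_example()), mode = "fill48")
  tps <- estimate_tps(cc)
  expect_identical(tps$label, c("mu", "delta_1", "delta_2", "delta_3"))
  expect_equal(round(tps$estimate, 2), c(0.67, 1.00, 0.50, 0.00))
  expect_true(all(tps$ci_low <= tps$estimate & tps$estimate <= tps$ci_high))
  # the longest observed attack cannot have continued
  expect_identical(tps$estimate[nrow(tps)], 0)

  omni <- estimate_omnibus(cc)
  expect_equal(omni$estimate, 0.6)
  expect_identical(c(omni$x, omni$n), c(3L, 5L))

  zero <- tally_transitions(map_states(diary("z", rep(0, 10))))
  mu0 <- estimate_tps(zero)
  expect_identical(mu0$estimate, 0)
  expect_identical(mu0$ci_low, 0)
  expect_error(estimate_omnibus(zero), "undefined")
})

test_that("zero-denominator parameters are skipped with a notice", {
  cc <- new_counts_for_test(onset_x = 1L, onset_n = 5L,
                            cont_x = c(1L, 0L, 1L), cont_n = c(2L, 0L, 1L))
  expect_message(tps <- estimate_tps(cc), "delta_2")
  expect_identical(tps$label, c("mu", "delta_1", "delta_3"))
})

test_that("omnibus estimate equals the collapsed-chain oracle", {
  withr::local_seed(31)
  for (rep in 1:50) {
    d <- fill48(random_diary(sample(10:80, 1), p = stats::runif(1, 0.1, 0.7)))
    cc <- tally_transitions(map_states(d, quarantine = TRUE))
    if (sum(cc$cont_n) == 0L) next
    om <- oracle_omnibus(d$migraine)
    expect_identical(sum(cc$cont_x), as.integer(om[["x"]]))
    expect_identical(sum(cc$cont_n), as.integer(om[["n"]]))
  }
})

test_that("weighted least-squares trend test recovers known slopes", {
  mk <- function(est, n) {
    structure(data.frame(label = paste0("delta_", seq_along(est)),
                         x = round(est * n), n = n, estimate = est,
                         ci_low = 0, ci_high = 1, conf = 0.95),
              class = c("tp_estimates", "data.frame"))
  }
  lin <- trend_test_wls(mk(c(0.2, 0.4, 0.6, 0.8), rep(50L, 4)))
  expect_equal(lin$slope, 0.2)
  # weights only matter up to scale
  expect_equal(trend_test_wls(mk(c(0.2, 0.3, 0.7, 0.6), c(10L, 20L, 5L, 40L)))$slope,
               trend_test_wls(mk(c(0.2, 0.3, 0.7, 0.6), c(20L, 40L, 10L, 80L)))$slope)
  flat <- trend_test_wls(mk(rep(0.4, 5), rep(30L, 5)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
  expect_error(trend_test_wls(mk(c(0.2, 0.4), rep(10L, 2))), "at least 3")
})

test_that("logistic trend test holds its size and gains power under a trend", {
  withr::local_seed(101)
  n_rep <- 200
  p_null <- p_alt <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    co0 <- simulate_cohort(n_patients = 25, n_days = 100,
                           params = chain_params(0.12, 0.5))
    p_null[r] <- trend_test_logistic(co0, mode = "fill48")$p_value
    co1 <- simulate_cohort(n_patients = 25, n_days = 100,
                           params = chain_params(0.12, c(0.25, 0.45, 0.65, 0.8)))
    p_alt[r] <- trend_test_logistic(co1, mode = "fill48")$p_value
  }
  size <- mean(p_null < 0.05)
  power <- mean(p_alt < 0.05)
  # size within 3 binomial SEs of the nominal 0.05
  expect_lt(abs(size - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_gt(power, 0.5)
})

test_that("logistic trend test flags degenerate input", {
  # every attack lasts exactly one day: only state 1 is ever at risk
  co <- cohort(diary("a", c(1, 0, 0, 1, 0, 0, 1, 0, 0)))
  expect_error(trend_test_logistic(co, mode = "fill48"), "contrast")
})

test_that("individual estimates summarise per-patient heterogeneity", {
  d <- fill48(worked_example())
  co <- cohort(lapply(1:4, function(j) {
    dj <- d; dj$patient_id <- paste0("p", j); dj
  }))
  ind <- individual_tps(co, mode = "fill48")
  expect_equal(ind$per_patient$mu, rep(2 / 3, 4))
  expect_equal(ind$per_patient$delta_omni, rep(0.6, 4))
  expect_equal(ind$summary$q2.5, ind$summary$q97.5)

  solo <- individual_tps(cohort(worked_example()), mode = "fill48")
  expect_equal(round(solo$per_patient$mu, 2), 0.67)
  expect_equal(solo$per_patient$delta_omni, 0.6)

  # a diary with no attack-state days yields a missing delta, with a message
  co2 <- cohort(worked_example(), diary("free", rep(0, 8)))
  expect_message(ind2 <- individual_tps(co2, mode = "fill48"), "excluded")
  expect_true(is.na(ind2$per_patient$delta_omni[2L]))
  expect_identical(ind2$summary$n_defined[ind2$summary$parameter == "delta_omni"], 1L)
})

test_that("per-patient spread tracks a known generating distribution", {
  withr::local_seed(53)
  co <- simulate_cohort(n_patients = 150, n_days = 250,
                        params = chain_params(0.15, 0.5),
                        delta_dist = function(n) stats::runif(n, 0.2, 0.8))
  ind <- individual_tps(co, mode = "fill48")
  s <- ind$summary[ind$summary$parameter == "delta_omni", ]
  # central-95% range of the estimates must cover the true inner quantiles,
  # inflated by estimation noise; generous Monte-Carlo margins
  expect_lt(s$q2.5, 0.35)
  expect_gt(s$q97.5, 0.65)
  expect_equal(s$median, 0.5, tolerance = 0.1)
})

test_that("the bootstrap is deterministic given a seed and degenerate on a
           degenerate cohort", {
  d <- fill48(worked_example())
  co <- cohort(lapply(1:6, function(j) {
    dj <- d; dj$patient_id <- paste0("p", j); dj
  }))
  b1 <- bootstrap_tps(co, B = 500, seed = 9, mode = "fill48")
  b2 <- bootstrap_tps(co, B = 500, seed = 9, mode = "fill48")
  expect_identical(b1, b2)
  # identical diaries: every resample gives the same pooled estimate
  expect_identical(b1$mu$ci_low, b1$mu$ci_high)
  expect_equal(b1$delta_omni$ci_low, 0.6)
  expect_error(bootstrap_tps(co, B = 10, mode = "fill48"), "seed")
})
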