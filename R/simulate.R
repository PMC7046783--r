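#' Generative chain parameters
#'
#' @param mu Onset probability: chance an attack begins on an at-risk
#'   (well-state) day.
#' @param delta Continuation probabilities: either a single
#'   duration-unconditional value, or a vector `(delta_1, ..., delta_n)`
#'   giving the chance an attack already `i` days long continues into day
#'   `i + 1`; attacks longer than `n` days keep using `delta_n` (the
#'   self-loop at the truncation state).
#' @param quarantine Logical; insert the deterministic post-attack
#'   quarantine day during which no new onset can occur.
#' @return A list of class `"chain_params"`.
#' @export
#' @examples
#' chain_params(mu = 0.085, delta = 0.509)
chain_params <- function(mu, delta, quarantine = TRUE) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0, mu <= 1,
            is.numeric(delta), length(delta) >= 1L,
            all(delta >= 0), all(delta <= 1),
            is.logical(quarantine), length(quarantine) == 1L)
  structure(list(mu = mu, delta = as.numeric(delta),
                 quarantine = quarantine),
            class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat(sprintf("Chain parameters: mu = %g, delta = (%s), quarantine %s\n",
              x$mu, paste(signif(x$delta, 4), collapse = ", "),
              if (x$quarantine) "on" else "off"))
  invisible(x)
}

#' Simulate a headache diary from the chain
#'
#' Starts in the well state and walks the chain one day at a time: from the
#' well state an attack begins with probability `mu`; on the i-th attack day
#' the attack continues with probability `delta_i` (a migraine-free day ends
#' it); with quarantine enabled, the day after the attack's first free day is
#' a quarantine day that returns deterministically to the well state. A day
#' is recorded as a migraine day exactly when the attack is ongoing on it.
#'
#' @param params A `chain_params`.
#' @param n_days Number of diary days to simulate (>= 1).
#' @param patient_id Id for the resulting diary.
#' @param seed Optional integer seed; when given, the global RNG state is
#'   left untouched.
#' @return A `diary`.
#' @export
#' @examples
#' simulate_diary(chain_params(0.2, 0.5), 30, seed = 1)
simulate_diary <- function(params, n_days, patient_id = "sim", seed = NULL) {
  stopifnot(inherits(params, "chain_params"), n_days >= 1)
  run_it <- function() {
    m <- logical(n_days)
    state <- 0L  # 0 = well, -1 = quarantine, i >= 1 = i-th attack day
    for (t in seq_len(n_days)) {
      if (state == -1L) {         # quarantine day: migraine-free, exit to well
        m[t] <- FALSE
        state <- 0L
      } else if (state == 0L) {   # at risk: onset?
        m[t] <- stats::runif(1) < params$mu
        state <- if (m[t]) 1L else 0L
      } else {                    # attack day `state`: continue?
        di <- params$delta[min(state, length(params$delta))]
        m[t] <- stats::runif(1) < di
        state <- if (m[t]) state + 1L
                 else if (params$quarantine) -1L else 0L
      }
    }
    diary(patient_id, m)
  }
  if (is.null(seed)) run_it() else withr::with_seed(seed, run_it())
}

#' Mask interior attack days (treatment-masking noise)
#'
#' Emulates single effectively-treated days inside ongoing attacks: each
#' interior attack day (a migraine day whose both neighbours are migraine
#' days) is independently flipped to migraine-free with probability `rho`,
#' except that a day whose left neighbour was just masked is never masked
#' (adjacent picks are suppressed, so no two masked days touch). Every
#' masked day is therefore a migraine-locked day of the output, and
#' [fill48()] recovers the original migraine record exactly.
#'
#' @param d A `diary`.
#' @param rho Masking probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A `diary` with the same days, some interior attack days flipped.
#' @export
#' @examples
#' d <- diary("p1", c(1, 1, 1))
#' apply_masking(d, rho = 1, seed = 1)  # M-M
apply_masking <- function(d, rho, seed = NULL) {
  stopifnot(inherits(d, "diary"), rho >= 0, rho <= 1)
  run_it <- function() {
    m <- d$migraine
    n <- length(m)
    if (n >= 3L) {
      prev_masked <- FALSE
      for (t in 2:(n - 1L)) {
        interior <- m[t] && d$migraine[t - 1L] && d$migraine[t + 1L]
        if (interior && !prev_masked && stats::runif(1) < rho) {
          m[t] <- FALSE
          prev_masked <- TRUE
        } else prev_masked <- FALSE
      }
    }
    out <- d
    out$migraine <- m
    out$imputed <- d$imputed & m  # a masked day loses any imputed mark
    out
  }
  if (is.null(seed)) run_it() else withr::with_seed(seed, run_it())
}

#' Simulate a cohort of diaries
#'
#' Generates `n_patients` diaries from the chain, optionally with
#' heterogeneous per-patient parameters, variable diary lengths, and
#' treatment masking. Defaults emulate the scale of a typical episodic-
#' migraine diary study: 165 patients, 108 days each, onset probability
#' 0.085 and omnibus continuation probability 0.509 with quarantine on.
#'
#' @param n_patients Number of diaries (default 165).
#' @param n_days Diary length: a single fixed length (default 108) or a
#'   range `c(min, max)` from which lengths are drawn uniformly (e.g.
#'   `c(71, 128)` to mimic an interquartile-range-like spread).
#' @param params A `chain_params` shared by all patients (default
#'   `chain_params(0.085, 0.509, quarantine = TRUE)`).
#' @param mu_dist,delta_dist Optional functions `n -> numeric(n)` drawing
#'   per-patient onset / continuation probabilities, overriding the shared
#'   values (continuations drawn this way are scalar per patient).
#' @param rho Treatment-masking probability applied to every diary
#'   (default 0, i.e. none).
#' @param seed Optional integer seed governing every draw.
#' @return A `cohort` with patient ids `p001`, `p002`, ...
#' @export
#' @examples
#' co <- simulate_cohort(n_patients = 5, n_days = 60, seed = 1)
simulate_cohort <- function(n_patients = 165, n_days = 108,
                            params = chain_params(0.085, 0.509),
                            mu_dist = NULL, delta_dist = NULL,
                            rho = 0, seed = NULL) {
  stopifnot(n_patients >= 1, inherits(params, "chain_params"),
            length(n_days) %in% 1:2, all(n_days >= 1),
            rho >= 0, rho <= 1)
  run_it <- function() {
    lens <- if (length(n_days) == 2L)
      sample.int(n_days[2L] - n_days[1L] + 1L, n_patients, replace = TRUE) +
        n_days[1L] - 1L
    else rep(as.integer(n_days), n_patients)
    mus <- if (is.null(mu_dist)) rep(params$mu, n_patients) else mu_dist(n_patients)
    deltas <- if (is.null(delta_dist)) NULL else delta_dist(n_patients)
    ids <- sprintf("p%03d", seq_len(n_patients))
    ds <- vector("list", n_patients)
    for (j in seq_len(n_patients)) {
      pj <- chain_params(mus[j],
                         if (is.null(deltas)) params$delta else deltas[j],
                         params$quarantine)
      dj <- simulate_diary(pj, lens[j], patient_id = ids[j])
      if (rho > 0) dj <- apply_masking(dj, rho)
      ds[[j]] <- dj
    }
    cohort(ds)
  }
  if (is.null(seed)) run_it() else withr::with_seed(seed, run_it())
}

#' Closed-form long-run migraine-day fraction
#'
#' For a scalar continuation probability the chain is a renewal process: a
#' cycle consists of a geometric wait in the well state (mean 1/mu days,
#' the last being the onset), an attack of mean length L = 1/(1 - delta)
#' migraine days, the free day on which the attack ends, and one quarantine
#' day if enabled. The long-run fraction of migraine days is therefore
#' L / (1/mu + L + c) with c = 1 if quarantine is enabled and 0 otherwise.
#'
#' @param params A `chain_params` with scalar `delta` < 1 and `mu` > 0.
#' @return The expected long-run fraction of migraine days.
#' @export
#' @examples
#' expected_migraine_fraction(chain_params(1, 0))          # 1/3
#' expected_migraine_fraction(chain_params(0.085, 0.509))  # ~0.1376
expected_migraine_fraction <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  if (length(params$delta) != 1L)
    stop("closed form requires a scalar (duration-unconditional) delta")
  if (params$mu <= 0 || params$delta >= 1)
    stop("undefined: requires mu > 0 and delta < 1")
  L <- 1 / (1 - params$delta)
  L / (1 / params$mu + L + if (params$quarantine) 1 else 0)
}
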