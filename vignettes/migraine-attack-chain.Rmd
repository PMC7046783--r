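---
title: "Counting and modelling migraine attacks from daily headache diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting and modelling migraine attacks from daily headache diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrainechain)
```

## The problem

Headache diaries record, for each calendar day, whether a patient had a
migraine. Studies often summarise such diaries as a migraine *frequency*
(migraine days per 30 observed days) without agreeing on what a discrete
migraine *attack* is. Two conventions make attack counts diverge: how runs
of consecutive migraine days are delimited, and how to treat single
migraine-free days wedged between migraine days. Clinically, headache that
returns within roughly 48 hours of relief is regarded as a relapse of the
same attack, so a single free day inside an otherwise continuous run — a
*migraine-locked day* — is best read as part of one attack rather than as a
boundary between two.

`migrainechain` implements a complete, deterministic pipeline built on that
reading:

1. **Fill48 imputation** — every migraine-locked day (a free day whose
   recorded neighbours on both sides are migraine days) is imputed as a
   migraine day and flagged as such.
2. **Attack segmentation** — attacks are maximal runs of consecutive
   migraine days; a run touching a diary boundary is censored.
3. **Markov-chain mapping** — each day is mapped to a state of an
   (n+2)-state discrete-time chain and contributes one transition event.
4. **Estimation** — onset and continuation probabilities with
   continuity-corrected Wilson score intervals, duration-trend tests,
   per-patient estimates, and a patient-level bootstrap.
5. **Simulation** — a seedable generator of the same chain, used both for
   study design and as the package's own test bed.

## The chain

The model has a well state $S_W$, attack-day states $S_1,\dots,S_n$, and an
optional quarantine state $S_Q$:

* From $S_W$ an attack begins with onset probability $\mu$ on each at-risk
  day.
* On the $i$-th attack day the attack continues into day $i+1$ with
  probability $\delta_i$; with probability $1-\delta_i$ the next day is
  migraine-free and the attack is over. The truncation bound $n$ is simply
  the longest attack observed; in the generator, attacks beyond the last
  supplied $\delta$ keep using it (the self-loop at $S_n$).
* $S_Q$ is the day after the attack's first migraine-free day. Under the
  Fill48 reading a migraine on that day would have made the free day
  locked — and hence imputed — so no new onset can be declared there: the
  exit back to $S_W$ is deterministic. Without Fill48 the quarantine state
  is dropped and the post-attack day is immediately at risk.

The omnibus continuation probability $\delta_{\mathrm{Omni}}$ pools all
attack-day states: the probability an attack continues, not conditioning on
how long it has lasted. If the $\delta_i$ are equal, the full chain
collapses to this three-state (or two-state, without quarantine) model.

### Day-to-state convention

States are assigned at the **start of day**: day $d$'s state is determined
by the record up to day $d-1$, and day $d$'s own record determines the
transition event realised during it. The first diary day is assumed to
start in $S_W$ (nothing is known before the record), so a migraine on day
one counts as an onset; symmetrically the final day contributes its event
as usual, and no day beyond the record is invented. This is the only
convention under which the worked example below reproduces all of its
published frequencies simultaneously; an end-of-day phrasing is the same
assignment shifted by one day. A consequence worth knowing: every attack's
first day is a well-state day, so the onset numerator equals the attack
count. The `--censor-edges` CLI flag instead drops each diary's leading run
from the tallies for users who prefer to treat the day-one state as
unknown.

## The worked example

A 9-day diary excerpt, days 29–37, migraine recorded on days 30, 32, 35
and 36:

```{r}
d <- worked_example()
d
segment_attacks(d)
find_locked_days(d)
```

Day 31 is migraine-locked; Fill48 merges the two flanking one-day attacks:

```{r}
di <- fill48(d)
segment_attacks(di)
map_states(di, quarantine = TRUE)
estimate_tps(tally_transitions(map_states(di)))
```

Days 29, 30 and 35 are at risk; two carry onsets, so
$\hat\mu = 2/3 \approx 0.67$, and the continuation frequencies are
$\hat\delta_1 = 2/2$, $\hat\delta_2 = 1/2$, $\hat\delta_3 = 0/1$. By
construction the last observed $\hat\delta$ is always zero: the longest
attack in the data did not continue.

## Estimation choices

**Intervals.** All proportions get the continuity-corrected Wilson score
interval, with the normal quantile computed exactly (not 1.96) and
endpoints clamped to $[0,1]$ (lower endpoint 0 when $x=0$, upper 1 when
$x=n$). Rounding to three decimals happens only at the reporting layer.
`stats::prop.test` implements the same interval and serves as an
independent cross-check in the test suite — note its correction is clamped
by the distance to the null proportion, so the cross-check passes a distant
null.

**Trend in $\delta_i$.** Two routes test whether continuation depends on
attack duration: a weighted least-squares regression of $\hat\delta_i$ on
$i$ with the observation counts as weights (two-sided t test on the slope;
a perfectly flat profile is reported as $p=1$ rather than the numerical
noise of a zero-residual fit), and a logistic regression of the day-level
migraine indicator on the number of preceding consecutive migraine days,
restricted to days at risk of continuing. The logistic covariate coding is
genuinely open — the day count can enter linearly (default) or as a
factor; both are provided, patients are pooled with a shared coefficient,
and separation is flagged rather than silently reported.

**Heterogeneity and uncertainty.** Per-patient estimates
$\hat\mu_j, \hat\delta_{\mathrm{Omni},j}$ are summarised by their median
and central 95% range; patients whose denominators are zero are reported
missing and excluded from the summary with a message. The bootstrap
resamples whole diaries with replacement to the original cohort size
(patients, not days, are the exchangeable unit), re-pools and re-estimates,
and reports the 2.5th–97.5th percentile interval (`quantile` type 7, the
percentile variant). A seed is mandatory; the default $B = 10^5$ is
desk-scale because per-diary counts are computed once and each replicate
only sums them ($B = 10^4$ is the CLI default).

## The simulator

`simulate_diary()` walks the chain a day at a time; `simulate_cohort()`
generates whole studies. The defaults are the study conditions the rest of
the package is exercised under: 165 patients, 108 days each (the package
also offers uniform lengths over 71–128 to mimic a realistic
interquartile spread), $\mu = 0.085$ and $\delta_{\mathrm{Omni}} = 0.509$
with quarantine on. Per-patient heterogeneity is injected by passing
sampling functions for $\mu_j$ or $\delta_j$; no particular mixing
distribution is canonical, so uniform ranges are used in the tests and
documented as an artifact choice.

With a scalar $\delta$ the chain is a renewal process, giving a closed-form
long-run migraine-day fraction
$$\frac{L}{1/\mu + L + c}, \qquad L = \frac{1}{1-\delta},$$
with $c=1$ when quarantine is enabled (the extra deterministic free day per
cycle) and $c=0$ otherwise. At the default parameters this is
$\approx 0.1376$, i.e. about 4.1 migraine days per 30 — the scale of an
episodic-migraine cohort. `expected_migraine_fraction()` evaluates it and
the test suite verifies the simulator against it with a block-resampled
Monte-Carlo standard error.

**Treatment masking.** `apply_masking()` emulates single effectively
treated days inside attacks: each interior attack day is flipped to
migraine-free with probability $\rho$. Adjacent flips are suppressed in a
left-to-right scan (an independent re-draw rule would never terminate at
$\rho = 1$ on long attacks), so every masked day is by construction a
migraine-locked day of the output and `fill48()` recovers the original
record exactly. This idealisation is deliberate: it keeps the synthetic
ground truth exact, at the price of not emulating multi-day treatment
effects, which Fill48 is explicitly not meant to repair.

What the generator does *not* emulate: hour-level timing, premonitory or
postdrome symptoms, medication records, seasonal or menstrual trigger
structure, missing diary days, or diagnostic (ICHD-style) attack criteria.
Passing tests therefore demonstrate internal correctness of the accounting
and estimation machinery under the stated model, not clinical validity on
any particular real diary corpus.

## Numerical and degenerate-input conventions

* Day numbers are 1-based and contiguous; gaps are errors unless the
  reader is told to split diaries at gaps.
* Boundary days are never locked (a neighbour is unobserved) and detection
  is simultaneous: imputation cannot create new locked days, so one pass
  suffices and Fill48 is idempotent.
* Mapping with quarantine refuses diaries that still contain locked days —
  a migraine inside the quarantine state is exactly the contradiction
  Fill48 exists to remove — and points the user at `fill48()`.
* Censored attacks are kept at their observed duration in all counts (no
  exclusion rule is canonical); `exclude_censored` provides the
  sensitivity analysis. Pooled mean attack duration is total migraine days
  over total attacks, which the tests verify against explicit averaging.
* Quantiles everywhere use linear interpolation (type 7); estimates with
  zero denominators are skipped or reported missing, always with a
  message, never silently dropped.
* Every stochastic function takes an explicit seed and restores the global
  RNG state; end-to-end runs are byte-for-byte reproducible given a config
  and seed.

## Problem sizes used by the test suite

The property tests enumerate all binary diaries up to length 10 (and
compare against brute-force oracles written from the verbal definitions),
plus 1000 random longer diaries. Parameter recovery runs one 165 × 108
cohort; bootstrap coverage runs 200 outer replicates at $B = 2000$; the
renewal closed form is checked on a single $10^6$-day simulation; the
logistic trend test's size and power use 200 replicates of 25 × 100
cohorts. These sizes keep each property's Monte-Carlo error small relative
to the 3-standard-error acceptance bands used in the assertions.

## Limitations

Fill48 imputes single-day gaps only — a two-day free gap is never locked,
by definition — and the package deliberately offers no generalisation to
longer gaps or to other conditions. The logistic trend test pools patients
without a clustering correction; with strong inter-patient heterogeneity
its p-values are anti-conservative, and the per-patient and bootstrap
machinery is the intended remedy. Transition probabilities are assumed
time-homogeneous within a diary; covariate-dependent transition matrices
are out of scope.
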