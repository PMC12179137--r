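---
title: "Modelling circadian blood-pressure profiles with circbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling circadian blood-pressure profiles with circbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circbp)
library(dplyr)
```

## The model and its assumptions

`circbp` describes one subject-day of blood pressure with a piecewise
exponential curve in five parameters: a nocturnal baseline `base` (mmHg), a
daytime increment `incr` (mmHg), a rate constant `k` (per hour) shared by
the morning rise and the evening/overnight decay, and the wake and bed
times `t1` and `t2` (decimal hours after midnight). During the wake phase
the pressure relaxes exponentially from `base` towards the plateau
`base + incr`; after bedtime it decays back towards `base`; before waking
it continues that overnight decay, with elapsed decay time measured from
the previous bedtime (`t + 24 − t2`). The three branches join continuously
at `t2` and at midnight by construction.

The assumptions this encodes: blood pressure is higher awake than asleep;
transitions are monotone and exponential (so predictions always lie in
`[base, base + incr]`); one set of parameters per calendar day
(midnight-to-midnight); and rise and fall share one rate `k`. Asymmetric
day/night dynamics, naps, and activity-driven excursions are outside the
model.

The *extended* variant re-assigns the pre-wake night segment to the
previous physiological day: its `base` and `incr` are replaced by the
previous day's fitted values (the current day's `k`, `t1`, `t2` are kept).
Carries are sequential and fixed — day `d` uses day `d − 1`'s estimates as
constants rather than co-estimating them, and if the previous day was
skipped the most recent fitted day supplies the carry. For a subject's
first fitted day no predecessor exists; it is fitted with the carry tied to
its own parameters, which makes the extended model collapse to the basic
one there. This was a genuinely open choice (alternatives: drop the
pre-wake segment of day 0, or borrow population values); tying the carry
keeps every day's likelihood defined on all of its data with no outside
information.

## Phase boundaries and bedtimes past midnight

The branch conditions are half-open: pre-wake on `[0, t1)`, wake on
`[t1, min(t2, 24))`, post-bed on `[t2, 24)`. Strict inequalities on both
sides would leave `t = t1` and `t = t2` unassigned; the chosen closures are
immaterial numerically because the curve is continuous at both joins.
Bedtime may exceed 24 h (bounded at 25 h, i.e. 1 a.m.): the post-bed branch
then becomes unreachable within the day, and the next morning's decay time
`t + 24 − t2` is floored at zero so the exponent never turns positive —
predictions stay within `[base, base + incr]` and continuous.

## Estimation

Each subject-day-channel is fitted independently ("double loop": subjects
outside, days inside), minimising unweighted squared error under the
port-style box constraints `base` ∈ 80–200 (systolic) or 20–120
(diastolic), `incr` ∈ 0–60, `k` ∈ 0.01–2, `t1` ∈ 1–11, `t2` ∈ 18–25.
Starting values are the day's minimum pressure for `base`, the day's range
for `incr`, and 0.3 / 5 / 22 for `k` / `t1` / `t2`, clipped into the box.
There is deliberately no pooling or random-effects structure across
subjects or days — the day is the unit of analysis, which is what makes the
intra-/inter-individual variability comparison possible.

The solver is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
relative function and parameter tolerances of `1e-10` and at most 200
iterations. Because the wake/bed breakpoints make the objective piecewise
smooth, the sum of squares can hold local minima in which the breakpoint
"parks" at a data point; the fit is therefore restarted from a fixed,
deterministic grid of additional starting values (`t1` ∈ {2, 3, 7, 9},
`k` ∈ {1.2}, crossed) and the lowest-sse solution kept. The supplied start
is always the first candidate, so the final objective never exceeds the
objective at the starting values. On noise-free test problems with truth
strictly inside the bounds this recovers all five parameters essentially
exactly; without the restarts (and equally with single-start `nls`/port)
slow-rise or early-wake days can stall several mmHg away from the optimum.
Fitting is fully deterministic.

Degenerate inputs: days with fewer than `min_obs = 6` observations (one
more than the number of parameters; the threshold is configurable) are
skipped and flagged rather than fitted. A constant day drives `incr` to its
lower bound 0, leaving `k`, `t1`, `t2` unidentified at whatever value the
solver settles on — the `converged` flag and `sse` remain meaningful.
Repeated timestamps are kept as repeated observations. If the solver stops
without meeting its tolerances the best iterate is returned with
`converged = FALSE`.

## Diagnostics and variability summaries

Weighted residuals are `100 · (observed − predicted) / observed` (%); the
sign convention (observed minus predicted) is a package choice — the
diagnostic is sign-symmetric. Summaries report per-parameter medians and
ranges (medians because day-level estimates are few and widely spread) and
coefficients of variation of `base` and `incr`, using the sample (n − 1)
standard deviation: per subject across its fitted days (intra-individual)
and pooled over all subjects' day-level estimates (inter-individual). The
pooled form was chosen over a CV of subject medians because the
inter-individual CV is meant to be computed across all subjects'
parameters; it also guarantees the overall range contains every subject's
range. Skipped days are excluded from all summaries; a CV over fewer than
two fitted days is reported as `NA`.

`bp_dipping()` converts parameters into the two clinically readable levels:
the nocturnal trough (the model's night-time limit, `base`) and the daytime
plateau (`base + incr`), plus the dip and dipping percentage.

## The synthetic-data generator

Because raw cuffless recordings of this kind are not redistributable, the
package generates its own test cohorts with known ground truth:
`bp_sim_config()` defaults emulate six healthy young adults wearing a
cuffless monitor for 14 days with on average 32 automated measurements per
day. Systolic population means (`base` 104, `incr` 16, `k` 0.33, `t1` 4.8,
`t2` 23.0) follow published overall medians for such a cohort; diastolic
means (`base` 62, `incr` 12) are scaled so that generated values span
roughly 41–85 mmHg against 74–140 mmHg systolic. Where no published value
exists, the spreads were set once to what is physiologically plausible and
produce the observed intra-vs-inter CV pattern: between-subject sds of
10 / 5 / 0.10 / 1.0 / 0.8 (systolic `base` / `incr` / `k` / `t1` / `t2`,
diastolic 7 / 4 for the pressures), within-subject day-to-day sds of 5 and
4 mmHg on `base` and `incr` only, and measurement noise of 5 (systolic) and
4 (diastolic) mmHg.

Generator mechanics: subject-level means are drawn from normals truncated
to the fitting bounds; `k`, `t1`, `t2` are drawn once per subject and
shared between channels (wake and bed times are traits of the person, not
of the pressure channel); each day perturbs `base` and `incr` (clipped into
bounds). Daily measurement counts are Poisson(32) and times uniform on
[0, 24) — the real device's trigger schedule is proprietary, so uniformity
is an assumption; night-time noise equals day-time noise. Measurements are
the basic-model curve plus Gaussian noise, with diastolic draws redrawn if
they reach their systolic partner.

What passing tests on this generator do *not* show about real data:
robustness to activity artefacts, position changes, device drift,
heteroscedastic night/day noise, or non-exponential transitions. They do
show that the estimation machinery recovers known parameters under the
stated sampling pattern and noise, and that the variability summaries
separate within- from between-subject spread when the latter dominates.

## Problem sizes and numerical checks used by the test suite

The suite fixes seeds everywhere. Noise-free recovery uses 48 evenly
spaced samples per day; solver-vs-oracle agreement is checked against an
exhaustive grid search over the full bounded box (1 mmHg grids on `base`
and `incr`, 0.01/h on `k`, 0.25 h on the clock times — made tractable by
profiling out the linear `base`/`incr` pair analytically). Noisy recovery
and the CV-pattern checks run the full default cohort (6 × 14 × ~32); the
CV pattern is required in at least 18 of 20 seeds. Continuity at bedtime
and midnight is asserted to near machine precision over 1,000 random
parameter sets.

## Known limitations

Per-day fitting means the basic model's pre-wake branch borrows the *same
day's* bedtime as a stand-in for the previous night's; the extended variant
corrects the night level but still uses the current day's `k`, `t1`, `t2`
there. Days are calendar days, so a subject whose sleep regularly spans
4 a.m. will have their night split across two fitted days. `k` is shared
between rise and decay; `incr` near 0 leaves the clock parameters
unidentified. No covariates, no cross-subject pooling, no cosinor-style
periodicity — by design the package describes profiles, it does not test
hypotheses about them.
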