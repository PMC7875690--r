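---
title: "Sedentary-behavior analytics from smartphone event streams: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sedentary-behavior analytics from smartphone event streams: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedkit)
```

## The measurement problem

Passive smartphone sensing can estimate when and where a person is
sedentary, but the raw material is awkward: to save battery, loggers record
an activity sample only when the state changes, update location only during
movement, and may be killed by the operating system at any time. sedkit
works from such an event stream — activity transitions, step deltas,
location fixes, screen events, in-app interactions, and a 20-minute
heartbeat — and turns it into hourly sedentary labels, personal sedentary
places, visualization aggregates, and evaluation statistics for a
baseline-vs-intervention design.

The heartbeat is the key design element. Without it, a silent logger is
indistinguishable from a still participant, and "phone off" would be counted
as sedentary time. Any record counts as liveness evidence; a silence longer
than `max_gap_minutes` (default 25 = the 20-minute heartbeat period plus 5
minutes of scheduler slack; the logging period is known but no gap tolerance
is prescribed anywhere, so the slack is our choice) is an outage gap.
Coverage is the window length minus the union of gaps, as a fraction.

## Hourly labels

Steps are summed into local clock hours, half-open `[h:00, h+1:00)` — an
event at exactly the boundary belongs to the later hour. An hour is
**sedentary** when it holds strictly fewer than 250 steps (roughly the two
minutes of walking per hour associated with reduced mortality risk, and the
hourly goal popularized by consumer trackers), **active** otherwise. Hours
whose covered fraction falls below `min_coverage` (default 0.5) are
**unknown**: a majority-silent hour is unknowable rather than sedentary.
Unknown hours are excluded from daily counts, not imputed; imputing them as
sedentary would inflate sedentary time exactly when the phone was off. Both
constants live in `label_config()`.

Sleep is *not* separated from sedentary time — daily counts include the
night. Change scores (intervention minus baseline, per participant)
difference sleep out under the assumption of stable sleep habits, which is
the quantity the evaluation uses. Timestamps are stored in UTC with an IANA
timezone attached at stream level, and all binning uses local clock time,
because days and hours as the user experiences them are local.

## Personal places

Place detection is the classic two-stage scheme: a **stay-point** scan
followed by a greedy spatial merge. A maximal run of consecutive fixes, all
within `dist_threshold_m` (50 m) of the run's first fix and spanning at
least `time_threshold_min` (10 min), becomes a stay point at the arithmetic
mean of its member coordinates; the scan resumes after each emitted run, so
stay points never overlap in time. Stay points are then processed
chronologically: each joins the first existing place whose centroid is
within `merge_radius_m` (50 m), moving that centroid to the
dwell-time-weighted mean, or founds a new place. Places with total dwell
under `min_sedentary_dwell_min` (30 min) are dropped, and the survivors are
ranked by total dwell. The exact clustering variant used by the original
app is not published, so this module is a standard, documented scheme with
all four knobs exposed in `place_config()` — a faithful stand-in rather
than a bit-exact port.

Distances are haversine on a 6371 km sphere; at the sub-kilometre scale of
daily life the spherical error is negligible and no projection is needed.
Each sedentary hour is linked to the place holding the majority of that
hour's stay-point dwell (ties to the earlier-founded place), at most one
place per hour — the table behind "tap a place, highlight its hours"
interactions. Because location is only updated during movement, a dwell is
bracketed by the arrival fix of the preceding movement and the departure
fix of the following one; dwells at the start or end of a recording have
only one bracket and may go undetected. The first morning and last evening
of a recording are therefore the places module's blind spots.

## Action plans

A plan is a when/where/how text triple. Specificity coding (3 = highly
specific, 2 = medium, 1 = vague) is deterministic and case-insensitive:
clock-time patterns, named places, and named activities are level 3;
recurring or event-anchored phrases ("every hour", "after lunch") and
large areas ("city", "university") level 2; empty or vague text level 1.
The vocabulary ships as a JSON lexicon
(`system.file("extdata", "specificity_lexicon.json", package = "sedkit")`)
rather than being hard-coded, because the reference coding was done by
human raters: a deployment can extend the term lists without touching code.
Non-empty text matching nothing is coded 2 and flagged `fallback` for
manual review — refusing to guess an extreme is the conservative error.
Highly specific matches are checked before vague ones, so "take a walk in
between experiments" codes 3 on the named activity rather than 2 on the
anchoring phrase.

Plan quantity is counted as total plans in a phase plus unique plans after
normalizing triples (trim, casefold, collapse whitespace). Quality measures
aggregate per participant first, then per group, so a prolific planner
cannot dominate a group mean. The plan store is append-only, mirroring the
app's no-deletion contract.

## Evaluation statistics

Small pilot groups (n = 8 per arm) make normal-theory p values fragile and
make "no effect" claims uninterpretable under significance testing alone,
so the evaluation pairs nonparametric tests with Bayes factors.

The default Bayesian t test contrasts H₀: δ = 0 against
H₁: δ ~ Cauchy(0, √2/2) on the standardized effect size. With t the
observed statistic, ν its degrees of freedom, and n_eff the effective
sample size (n for paired designs, n₁n₂/(n₁+n₂) for two-sample),

BF₁₀ = ∫ f(t | ν, δ√n_eff) dCauchy(δ; 0, r) / f(t | ν, 0),

where f is the noncentral t density. One-sided factors (BF₊₀, BF₋₀)
truncate and renormalize the prior on a half-line, so
BF₊₀ + BF₋₀ = 2·BF₁₀ identically. The correlation test uses the exact
sampling density of the observed Pearson r integrated over a stretched-beta
prior on ρ (width κ = 1, i.e. uniform on (−1, 1)). Everything is
deterministic adaptive quadrature — no MCMC — after the change of variables
δ = r·tan(u), which absorbs the Cauchy density into the measure and keeps
the integrand bounded for any prior scale. Relative tolerances are 1e−8 or
tighter; posterior medians and 95% intervals come from numerical CDF
inversion in the same coordinate. Tests verify the implementation against
an independent Simpson-rule oracle at much finer resolution, and the
identities BF₀₁·BF₁₀ = 1 and BF₊₀ + BF₋₀ = 2·BF₁₀ to 1e−6.

The nonparametric side reports normalized Z statistics with tie-corrected
variances. The signed-rank test additionally reports the centered S
statistic (positive-rank sum minus its null mean n(n+1)/4), since some
commercial statistics packages print that scale rather than Z for small
samples. Spearman p values use the large-sample deviate Z = ρ√(n−1); at
n = 8 that approximation is rough, which is inherent to the design size,
not to the implementation.

When Bayes factors are reconstructed from *printed* summary statistics
(means and SDs rounded to two decimals) rather than raw data, the rounding
alone moves the result by a few percent; reproduction is therefore judged
within ±0.1 absolute or 7% relative, whichever is larger.

## The simulator

`simulate_participant()` generates streams with the logger's semantics:
change-only activity records, per-minute integer step deltas whose hourly
sums hit the programmed rates exactly (cumulative rounding), fixes only
during movement with Gaussian GPS noise, heartbeats every 20 minutes, and
configurable outages that silence everything. The default day is an office
worker among three places (home, office, a lunch spot), giving 21 sedentary
hours per day including the night — deliberately on the high side of
realistic, making label arithmetic easy to audit. `simulate_study()` builds
the three-phase timeline (excluded entry day, 7 baseline days, excluded
mid-study day, 14 intervention days, excluded exit day) with alternating
group assignment and a group-specific injected effect: from the first
intervention day, the tail of the day's latest sedentary block is converted
to walking, with fractional effects spread over days by cumulative rounding
so a −0.5 h/day target flips one hour on every second day.

What the simulator does *not* emulate: day-to-day schedule variability,
weekends, location drift indoors, activity-recognition confusion, or
correlated outages. Passing end-to-end tests therefore show that the
pipeline inverts the logging semantics correctly — labels equal ground
truth at full coverage, programmed places and effects are recovered — not
that it is robust to every messiness of field data. Test problem sizes
(2-7 simulated days for unit tests, 8 + 1 participants over 23 days for
the parameter-recovery check) were chosen as the smallest sizes that
exercise every code path, including the study's own group size of eight.

## Numerical and degenerate-input choices

* Timestamps are quantized to milliseconds, the log format's resolution, so
  write-then-parse is bit-exact (doubles are serialized at 17 significant
  digits for the same reason).
* Ties at identical timestamps sort by kind order then input order —
  deterministic outputs everywhere.
* A pooled two-sample t with both SDs zero is an error, as is a paired
  summary with zero SD; the published analysis hit the same wall (one
  group's how-specificity had SD 0 and its Bayes factor went unreported).
* A Bayes factor at |r| = 1 is unbounded; the engagement association
  reports no finite value there rather than a fabricated one.
* Labeling an hour with coverage exactly at `min_coverage` is labelable
  (the comparison is strict `<`).

## Known limitations

Posture is not inferred — sitting, standing, and lying are one class, a
limitation of step-count sensing itself. Sleep is not detected. Stay-point
detection cannot see dwells that lack movement brackets at recording
boundaries. The specificity lexicon covers the published vocabulary and
common variants; out-of-vocabulary plans fall back to level 2 with a review
flag rather than being coded confidently.
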