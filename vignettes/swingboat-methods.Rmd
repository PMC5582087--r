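---
title: "Methods: sleep, exercise and survival scoring for DAM recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep, exercise and survival scoring for DAM recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swingboat)
```

This vignette is the package's own account of what it computes and why: the
scoring rules and their boundary conventions, the statistics, the simulator's
model and what it does and does not emulate, and the design choices that were
genuinely open.

## Data model

A DAM monitor logs beam crossings per recording interval for 32 channels.
`read_monitor_file()` parses the common tab-separated monitor export (index,
date, time, status code, five padding fields, light flag, 32 counts; other
layouts via `dam_dialect()`). Timestamps mark the **start** of each counting
interval and are timezone-naive local time; all Zeitgeber arithmetic goes
through `light_schedule()` (ZT0 = lights-on, default 08:00, LD12:12).
Readings with a status code other than 1 are kept but masked, never silently
dropped; downstream scoring treats masked bins as missing. Files with
out-of-order lines are rejected unless re-sorting is requested explicitly.

The native resolution is 1 minute. 5-minute files are accepted; scoring on
them is an approximation (below) and results carry the bin size used.

## Sleep scoring

Sleep follows the standard fly convention: a **sleep bout** is a maximal run
of zero-count minutes lasting at least 5 min (`threshold_min`, default 5).
Bouts of at most 60 min are **short-term (fragmented) sleep**; bouts longer
than 1 h are **long-term sleep** — a bout of exactly 60 min is short. Bout
boundaries are half-open minute intervals: start = first zero minute, end =
last zero minute. On 5-min bins, one zero bin contributes 5 sleep minutes and
already satisfies the 5-min rule; this over-counts sleep relative to 1-min
scoring whenever a bin mixes activity and rest, which is why the mode is
labeled. Masked bins interrupt a zero run: sleep is never asserted across
unobserved time.

Raising the threshold can only remove bouts, so total sleep is monotone
non-increasing in the threshold (a property the test suite asserts).

## Death calling

A fly is dead when its **terminal** run of zero counts exceeds 24 h
(`immobility_hours`, strict inequality: exactly 24 h of terminal zeros is
still censored alive). The death time is the end of the last bin with a
nonzero count — the lifespan runs to the last observed movement; the
alternative convention (last movement + 24 h) is available by option. A
mid-recording immobility run followed by renewed activity is never a death.
A fly with no counts at all has no usable time origin: it is called dead at
the series start, flagged `never_active`, and dropped from survival records
by default for manual review. Death calling is idempotent under appending
further zeros.

## Days and behavioral episodes

Each bin belongs to one of four clock-time episodes: night 22:00–04:00
(ZT14–20), morning 04:00–12:00 (ZT20–4), siesta 12:00–16:00 (ZT4–8), evening
16:00–22:00 (ZT8–14). They are disjoint and tile 24 h (6 + 8 + 4 + 6).

Days are anchored at lights-on and numbered from 1. The morning window spans
ZT20–ZT4, i.e. a day boundary; each bin is assigned to the day of its ZT
timestamp **except** that the pre-dawn portion (ZT20–24) attaches to the
following day, keeping every morning episode contiguous within one day. This
was a genuinely open choice (attaching to the preceding day is equally
defensible); attaching forward means "the morning of day d" is the morning
the fly wakes into day d. A consequence is that the first experiment day
lacks its pre-lights-on segment (20 of 24 h present). `summarize_daily()`
therefore includes a day when at least a fraction `min_coverage` (default
0.8) of its 1440 minutes is present and unmasked: day 1 (0.83) is retained, a
trailing 4-h fragment (0.17) is dropped, and a D-day recording yields exactly
D daily summaries.

Sleep minutes are attributed bin-by-bin from the bout cover, so a bout
spanning an episode boundary splits pro-rata by overlap and per-episode sums
reconcile exactly with daily totals (asserted in the tests). Days at or after
a called death carry `alive = FALSE` and no behavioral values; all group
averaging is living-only.

## Exercise success

The rocking protocol is a `stimulus_schedule()`: default 30 min from ZT7,
3 stimuli/min (90/day), displacement 30° at 30°/s with a 17 s pause, active
days 1–12; `build_stimulus_schedule()` expands it to explicit per-day
stimulus times at the even `60/rate`-second spacing.

One hundred percent success means at least one detected movement after each
stimulus. How individual responses are resolved depends on resolution:

- **fine mode** (bins no coarser than the inter-stimulus interval): stimulus
  *i* succeeds if its response window `[t_i, t_{i+1})` — a count is
  attributed to the most recent stimulus; the last window closes at the
  session end — contains ≥ 1 count; success = responding stimuli / stimuli.
- **capped mode** (e.g. 1-min bins with 3 stimuli/min, where individual
  responses are not resolvable): success =
  `Σ_bins min(counts_in_bin, stimuli_in_bin) / total stimuli`. A bin cannot
  witness more responses than it received stimuli, so the estimate stays in
  [0, 100]; 1 count/min over the 30-min session gives 30/90 = 33.3%.

The capped estimator is this package's construction for coarse data; results
carry a `mode` attribute. It is exactly unbiased when window counts are
stimulus responses (0/1 per stimulus): `E[min(Binomial(3, p), 3)] = 3p`.
Counts unrelated to the stimuli inside the window inflate it, up to the cap —
so it is **not** bounded by the fine estimator for arbitrary event streams
(three counts clustered after one stimulus count as three under the cap but
as one response when resolved); the two agree whenever responses are binary,
which the tests assert. Success is invariant to counts outside the window.

Per fly, success is averaged over its valid active days (fly-days at or after
death are excluded); the group summary is the median and 25th/75th
percentiles of the fly means, the statistics of a Tukey-whisker box plot.
`exercise_share()` relates exercise-window counts to the voluntary
morning + evening peak activity of the same day (a percentage, averaged over
active days; days with zero peak activity are excluded and flagged).

## Survival analysis

`km_estimate()` implements the Kaplan–Meier product-limit estimator directly:
S(t) = ∏ (1 − d_i/n_i) over event times t_i ≤ t, censored flies leaving the
risk set after their censoring time. With no censoring it reproduces the
empirical survivor function exactly. The median is the smallest event time
with S(t) ≤ 0.5 (the standard convention: deaths {1, 2, 3, 4} have median 2);
a curve that never reaches 0.5 has no median (`NA`, "not reached").
`logrank_test()` is the two-sample Mantel–Cox test with the hypergeometric
variance for ties, 1 df. Both are cross-checked in the test suite against an
independent reference implementation (the `survival` package) to 1e-9, and
the log-rank null rejection rate is calibrated by simulation. The
implementations were written here rather than delegated so that the reference
package can serve as a genuinely independent oracle.

Time origin is the start of recording; death days are fractional (bin
resolution / 1440). Flies alive at the end are censored at the last
timestamp. `median_prolongation()` reports treated − control in days and as a
percentage of the control median (28.5 vs 21.5 days → 7.0 days, 32.6%).

Two conventions worth noting when comparing a recovered KM median with a
planted distribution median: the lifespan-to-last-movement rule places the
death slightly before the true death (by however long the fly slept before
dying), and the S(t) ≤ 0.5 convention picks the ⌈n/2⌉-th order statistic
rather than interpolating. Both shift the recovered median slightly downward;
at n = 32 the combined effect is a fraction of a day.

## Group statistics

`daily_living_mean()` gives per-day mean ± SEM over living flies (SEM 0 by
convention at n = 1, flagged by the n column). `relative_to_control()`
expresses a group as a percentage of its control (control = 100%) per day,
and summarises day ranges (default 1–12 and 13–20) under **both**
conventions — the mean of per-day ratios and the ratio of range-averaged
means — because they differ whenever the daily ratio varies and published
range percentages do not always state which was used; both are reported,
labeled.

`compare_groups()` is two-tailed. "Student's t-test" is ambiguous between
pooled and unequal-variance forms; the default is Welch (robust to unequal
variances), pooled available by flag. Mann–Whitney uses the exact null when
the combined n ≤ 20 without ties, and the tie-corrected normal approximation
above. Zero variance in both samples with equal means returns p = 1. Stars
follow the usual convention (* < 0.05, ** < 0.01, *** < 0.001). No
multiple-testing correction is applied, and the report tables say so.
`box_summary()` fixes the quartile definition to linear interpolation
(R type 7) and Tukey whiskers at the most extreme points within 1.5 × IQR.

## Actograms and daily profiles

`actogram_matrix()` lays a series out as days × 288 five-minute ZT-aligned
columns (column k covers ZT minutes [5(k−1), 5k)); partial edge days and
masked bins are `NA`, so the matrix total equals the series total.
`render_actogram()` draws single-plotted per-day bar rows (double plotting by
flag) with a yellow/gray LD bar and a red frame over the exercise window on
active days; missing bins render as gaps, and output is deterministic for
fixed input and device settings. `daily_profile()` averages whole living
fly-days into a 288-bin mean profile, with the same living-only rule as the
group statistics.

## The simulator

`simulate_fly()` generates per-minute series with the statistical structure
the pipeline assumes, so the whole package runs with no external data:

- **Sleep/wake**: a two-state per-minute Markov (alternating-bout) process.
  Mean wake and sleep bout durations (defaults 20 and 40 min) are modulated
  by a circadian sleep-drive template — 3× at night, 2.5× in the siesta,
  0.4× around the activity peaks — and a **fragmentation factor**
  multiplies both bout-exit rates, shortening bouts without changing the
  equilibrium sleep fraction.
- **Activity**: wake minutes emit Poisson counts from an intensity template
  (baseline 1.2 counts/min with siesta and night suppression, plus Gaussian
  morning and evening peaks at ZT0.5 and ZT11.5), scaled by a per-day age
  trend; sleep minutes emit 0.
- **Nocturnal spiking**: short (2–4 min) wake bursts of elevated counts
  inserted during the dark phase at a planted per-night rate.
- **Exercise**: on active days, the stimulation window overrides spontaneous
  behavior — each of the 90 stimuli independently elicits one count, in the
  minute containing the stimulus, with probability `p_resp`. The override
  reflects the forced nature of the rocking (normal siesta behavior is
  preempted) and makes the capped success estimator unbiased for `p_resp`.
- **Mortality**: death times are log-normal, parameterized directly by the
  median with log-scale SD 0.2 — a deliberately tight, realistic cohort
  spread; all counts after death are zero.

Determinism: each fly draws from its own seed substream derived from the
master seed, so enlarging a cohort or adding groups never reshuffles existing
flies.

`default_profiles()` bundles four calibration profiles — wild-type-like,
driver-like (low responder), reporter-like, and AD-like (high responder,
8 nocturnal spikes/night, fragmentation 2.2, reduced night sleep drive,
median survival 21.5 days stationary / 28.5 exercising) — with per-stimulus
response probabilities 0.3862, 0.0944, 0.4176, 0.4814 and the corresponding
stationary/exercising survival medians (40/38, 27/31, 35/34, 21.5/28.5
days).

The simulator's **bout truth** is the log of maximal zero runs of the emitted
counts. A wake minute in which the fly happens not to cross the beam is
indistinguishable from rest — in real DAM data as in the simulation — so the
truth is defined at the level the instrument observes; detector correctness
is established separately against a brute-force maximal-zero-run oracle.

What the simulator does **not** emulate: position within the tube (single
beam only), post-exercise rest compensation or sleep redistribution (plantable
via profile deltas but off by default), arousal thresholds, circadian period
drift, temperature effects, and social effects (flies are independent).
Passing recovery tests therefore demonstrates that the pipeline measures what
the generative model plants — not that real flies satisfy the model.

## Problem sizes and numerical choices

The bundled checks use cohorts of 32 flies (one monitor). Exercise-success
recovery simulates 13 recording days (12 exercise days plus the trailing
fragment); survival recovery simulates 45 days so that essentially the whole
cohort dies before the end. Comparisons against the reference survival
implementation use 200 mixed-censoring records at tolerance 1e-9; the
log-rank type-I rate is checked over 1000 null simulations at n = 32 per arm.
Degenerate inputs are handled explicitly: empty monitor files round-trip to
empty tables, all-masked series warn and score nothing, all-censored cohorts
report "median not reached", and zero-variance group comparisons return
p = 1 rather than failing.
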