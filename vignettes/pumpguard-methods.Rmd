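---
title: "pumpguard: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pumpguard: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pumpguard)
```

## The data model

A DERS (dose-error-reduction software) log is a stream of time-stamped
events per pump module: program selections, soft/hard/concentration limit
alerts, overrides, reprograms, cancellations, and infusion starts (library,
basic mL/h, or drug calculator — the latter two record no medication name).
Pump clocks report whole seconds, and one modular pump (a *device*) carries
up to four large-volume, syringe, or PCA *modules*. Events belonging to one
alert episode share a *sequence id* on one module.

Vendor export dialects are proprietary, so the package defines an open CSV
schema (`read_event_log()`, `log_dialect()`) with a column map for adapting
other delimited exports. Timestamps are ISO-8601 local time; no time-zone
arithmetic is attempted because every statistic the package computes is a
second-level difference within one facility. Unparseable rows are
quarantined with a reason, never silently dropped: row conservation
(`parsed + quarantined = input`) is a tested invariant.

The formulary model mirrors the pump interface: a 20-character core name,
an optional 20-character therapy line, per-profile dose and concentration
limits. Names are stored verbatim — TALLman capitals preserved — and every
comparison goes through `normalize_name()`.

## Pairing cancellations with corrections

A near-miss correction appears in the log as a cancellation rapidly followed
by a new program. `pair_cancellations()` matches each cancelled sequence to
the earliest not-yet-claimed confirmed program on the *same device* whose
first event falls within the window `w` (default **120 s**; the longest
correction latencies plausibly seen in practice are under two minutes, and
the default truncation bound of the simulator is 116 s). Greedy
earliest-first matching on a device timeline is a maximum matching here, so
the number of paired cancellations is non-decreasing in `w` — a tested
property.

The same *module* is preferred, but a sibling module on the device is
accepted and flagged (`cross_module`): a wrong-channel error — a PCA
medication first loaded on a syringe driver — is by nature corrected on the
other module, so module-strict pairing would make that category
unobservable.

Two decision-time conventions are exposed, anchored on the two unambiguous
log events: `cancel_to_correct` (replacement confirmation − cancellation,
the default) and `select_to_cancel` (cancellation − erroneous selection,
the recognition time). Negative latencies (clock regressions) reject the
pair and are flagged.

## The cause ladder

Classification is a first-match ladder, ordered so that categories with
dedicated log evidence cannot leak into weaker ones:

1. **Concentration-limit breach** — the cancelled sequence contains a
   concentration-limit alert. These are filed by the pump under the
   hard-limit ("reprogram limit") alert group, so they count toward that
   alert category and are excluded from the cancellation-share denominator
   (their share is reported against all alerts).
2. **Calculator exit** — the replacement is a drug-calculator start.
3. **Wrong channel** — same normalized name, PCA↔syringe module swap.
4. **Incorrect medication** — normalized names differ.
5. **Wrong dose** — same name; dose or concentration differs after unit
   normalization beyond a relative tolerance of 1e-6 (guarding against
   float-format artefacts masquerading as dose changes).
6. **Indeterminate** — everything else: unpaired cancellations, identical
   reprograms, and nameless basic-mode replacements (flagged). Plausible
   real-world causes include IV-access failure, patient-condition change
   and therapy discontinuation, none of which the log can distinguish.

Name comparison case-folds TALLman capitals and collapses whitespace but
keeps therapy suffixes: a therapy mix-up is still a wrong-entity selection
at the pump. Dose units convert within a dimension (mass, activity, volume,
amount-of-substance); compound units must agree in their weight/time
denominators; incompatible dimensions yield `NA` rather than a guess, and
unitless doses are excluded from factor statistics.

The **dose-error factor** is cancelled dose ÷ corrected dose in common
units. Factors below 1 (potential underdoses) are retained and summarized
together with the count of *extreme* factors above a configurable threshold
(default 100×).

## The divergence-position rule

Published example pairs of cancelled/corrected names label *where* the
misreading happened (name beginning, middle, end), but no formal rule for
that judgment exists. The package's default `char_thirds` rule is:

* normalize both names (case fold, collapse whitespace, keep therapy text —
  the published pairs include it);
* let *i* be the common-prefix length and *L* the length of the **shorter**
  name (the reading field both names share);
* class by *i/L*: BEGINNING on [0, 1/3), MIDDLE on [1/3, 3/5), END on
  [3/5, 1].

The boundaries were **calibrated against the ten published example pairs**:
with the shorter-name denominator and cut points 1/3 and 3/5 the rule
reproduces 8 of the 10 printed labels, and the two discordant rows are
exactly the two that defy any simple positional rule we tried (a
second-word difference printed as *end*, and a short-prefix pair printed as
*middle* — both plausibly judged by discriminating syllable rather than
character position). Those two rows are frozen in the test suite with their
*computed* classes so any change to the rule is visible. A `word_token`
mode (class of the first differing whitespace token) is provided as the
plausible alternative reading; it is not the default because it reproduces
fewer printed labels. The rule is symmetric in its arguments and the three
classes are exhaustive and mutually exclusive — both tested properties.

## The synthetic facility

`generate_log()` simulates the log of a facility over a study year. Its
defaults *are* the observed study conditions, not tuning knobs:

| quantity | default |
|---|---|
| alert mix (hard, soft, cancelled, other) | 13.81 / 48.65 / 15.37 / 22.17 % |
| cancellation causes (wrong med : wrong dose : indeterminate : wrong channel : calculator) | 10017 : 8533 : 26144 : 17 : 10 |
| concentration-limit cancellations | 603 per 40,184 hard-limit alerts |
| divergence positions (beginning, middle, end) | 69.79 / 21.40 / 8.81 % |
| correction latency | log-normal, mean 27.00 s, SD 22.25 s, truncated to 4–116 s |
| dose-error factor | log-normal, median 1.5, sdlog 0.8, + exactly 11 planted extremes in (100, 500] |
| library compliance | 74.29 % |
| alerts per library start | 290807 / 1050531 ≈ 0.277 |

Notes on the modelling choices:

* **Latencies** are right-skewed and positive with median below the mean
  (observed median ≈ 20 s against mean 27 s), which a log-normal captures.
  The `(meanlog, sdlog)` pair is solved numerically (closed-form truncated
  moments + Nelder–Mead) so the *truncated* distribution has the target
  mean and SD; matching the untruncated moments and then truncating would
  bias the realized mean by roughly 0.7 s. Draws use inverse-CDF sampling,
  so truncation is exact; planted latencies are rounded to whole seconds,
  the pumps' clock resolution. A Kolmogorov–Smirnov check against the
  truncated distribution at n = 10,000 is part of the suite.
* **Dose factors**: the observed mean (≈14.5) is dominated by a handful of
  extreme outliers; a parametric tail would reproduce their count only in
  expectation. The generator therefore plants *exactly*
  `extreme_outlier_count` uniform draws from `extreme_factor_range` and
  leaves the log-normal bulk (sdlog 0.8, chosen so the bulk essentially
  never crosses the 100× threshold) for the rest. Underdose factors occur
  naturally and are kept.
* **Indeterminate cancellations** are realized half as cancellations with
  no replacement inside the window and half as identical reprograms,
  mirroring the two log signatures the category can take.
* **Arrivals** are homogeneous-Poisson-like per device with a guard gap of
  150 s (> the 120 s pairing window) between programs, an explicit and
  replaceable assumption. Its purpose is determinism of recovery: on
  default settings no foreign program can fall inside a cancellation's
  pairing window, so the pipeline must recover 100% of planted causes,
  latencies to the second, and every planted extreme factor — all asserted
  against the ground-truth file.
* **Scale**: devices carry two modules with the facility's module-type mix
  (large-volume : syringe : PCA ≈ 3662 : 846 : 62); a small share of
  devices carries a syringe+PCA pair to host wrong-channel events. The
  module count scales as one per ~400 starts.

What the generator does **not** emulate: titration dynamics, per-patient
structure (the data model is patient-anonymized by design), clinical
advisories, care-area-specific alert rates, clock drift between devices,
and vendor-dialect quirks. Passing recovery tests on synthetic logs
therefore demonstrates the *pipeline's* correctness, not that real logs are
this clean — real exports should be triaged with `validate_log()`
(orphan resolutions, duplicate sequence ids, time regressions, misrecorded
basic/calculator names) before analysis.

## Reporting conventions

Percentages are exact quotients rounded half-up to two decimals and are
always emitted beside their numerator and denominator. Published tables of
this kind sometimes mix truncation and rounding (e.g. a printed 15.37 where
exact division gives 15.378, or 8.80 vs 8.81 for the same 882/10,017); the
package never replicates a printed variant — it reports the exact quotient
and leaves reconciliation to documentation like this paragraph.

## Problem sizes and determinism

The test suite validates the statistical recovery end-to-end on a simulated
facility of 50,000 library starts (~145,000 events, ~2,100 cancellations),
with alert- and cause-mix recovery checked against exact 99% binomial
intervals, the latency mean against a 3-standard-error band, and extreme
dose factors for zero false negatives; smaller logs (200–4,000 starts)
cover unit-level behaviour. `scripts/acceptance.R` re-runs the 50,000-start
analysis from scratch for any seed. All randomness flows from the single
generator seed; identical config and seed reproduce the log byte for byte
within one R version (cross-implementation reproducibility is promised at
the level of statistics, not bytes).

## Known limitations

* The cause ladder can only see what the log records: a wrong dose
  corrected by cancelling and re-selecting the same dose via the calculator
  is classified as a calculator exit, and corrections that take longer than
  the pairing window become indeterminate.
* Name analytics are visual (edit distance, prefix structure); phonetic
  (soundalike) similarity is out of scope.
* The divergence-rule boundaries are calibrated to ten published pairs;
  with larger labelled corpora they should be re-estimated.
* Compliance counts starts, not volumes or durations.
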