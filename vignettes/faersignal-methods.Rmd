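---
title: "Methods: disproportionality signal detection on FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems such as the FDA Adverse Event
Reporting System (FAERS) collect unsolicited reports of suspected drug-event
associations. They have no denominator of exposed patients, so risk cannot be
estimated directly; instead, *disproportionality analysis* asks whether a
drug-event pair is reported more often than the database background would
predict. `faersignal` implements that workflow end to end for a single target
drug: ingestion of the quarterly DEMO/DRUG/REAC/THER tables, case
deduplication, primary-suspect selection, per-term 2×2 contingency tables,
four disproportionality statistics with a conjunction signal rule,
time-to-onset (TTO) modelling, and descriptive summaries. A seeded synthetic
generator with a ground-truth answer key makes every stage testable without
access to the real database.

## Data model and preprocessing

A quarter consists of four delimited tables sharing a case identifier:
demographics (one row per *report version*), drugs (role codes PS/SS/C/I:
primary suspect, secondary suspect, concomitant, interacting), reactions
(MedDRA Preferred Terms, PTs), and therapy dates. Two dialects are read: the
FDA's `"$"`-delimited ASCII layout and a comma-separated variant with the
same column names. Rows whose field count disagrees with the header are
counted in a provenance log and skipped; they are never fatal.

**Deduplication.** Databases of this kind carry multiple versions of the
same case. We retain, per case identifier, the version with the most recent
FDA receipt date, breaking ties by the highest version number and then by
last-seen input order; absent dates sort lowest. The operation is
idempotent, and the final tie-break makes it deterministic for any input
ordering.

**Dates.** Receipt, event and therapy-start dates are 8-digit `YYYYMMDD`
strings, but partial dates (`YYYYMM`, `YYYY`) are common in practice.
Partial dates are retained with a precision flag rather than discarded:
yearly counts only need the year, while TTO requires day precision on both
ends. Completeness filtering therefore removes only cases lacking any drug
or any reaction row; event-date completeness is enforced inside the TTO
module alone, so a case with a partial event date still contributes to
signal detection.

**Drug names.** Verbatim names are lower-cased, trimmed, and
punctuation-collapsed, then mapped through a synonym table to an ingredient
name. The shipped table covers the roflumilast brand names (Daliresp,
Daxas) and is user-extensible; unmapped names pass through normalized.

## Contingency tables

The counting unit is the **distinct (case, PT) pair**: a case reporting
*k* distinct PTs contributes *k* pairs, while a PT mentioned twice in one
case counts once. For each term, with the target set defined by
primary-suspect selection,

|              | term          | other terms |
|--------------|---------------|-------------|
| target drug  | *a*           | *b*         |
| other drugs  | *c*           | *d*         |

the margins *a + b* (total target pairs) and *c + d* (total background
pairs) are constant across terms. The background is every deduplicated case
not in the target set — including cases that carry the target drug in a
non-PS role. System Organ Class (SOC) tables sum the member PTs' *a* and
*c* cells (cumulative occurrences, so SOC totals may exceed the case
count — a case reporting three gastrointestinal PTs contributes three) and
recompute *b*, *d* from the fixed margins. The background universe is
whatever was ingested; no additional windowing is applied.

## The four statistics and their conventions

All four statistics are algebraic functions of one table, with a shared
log-normal standard error
$SE = \sqrt{1/a + 1/b + 1/c + 1/d}$:

* **ROR** $= ad/(bc)$, CI $= \exp(\ln ROR \pm 1.96\,SE)$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with Pearson's uncorrected
  $\chi^2 = \frac{(ad-bc)^2\,N}{(a+b)(c+d)(a+c)(b+d)}$.
* **IC** $= \log_2\frac{aN}{(a+c)(a+b)}$ (the BCPNN information component in
  its simplified, non-Bayesian form), with
  $IC_{025} = IC - 1.96\,SE/\ln 2$.
* **EBGM** $= \frac{aN}{(a+c)(a+b)}$, the observed/expected relative
  reporting ratio (no gamma-Poisson shrinkage; a full MGPS posterior is out
  of scope), with $EBGM_{05} = \exp(\ln EBGM - 1.96\,SE)$.

Two conventions deserve comment. First, $IC_{025}$ is computed *linearly*
on the log2 scale rather than by exponentiating: an exponentiated bound
could never be negative, yet SOC-level reference values plainly are, and the
linear form reproduces the published lower bounds from the published ROR
intervals (the acceptance suite reconstructs the most frequent published
signal's $EBGM_{05}=3.55$ and $IC_{025}=1.82$ this way). Second, despite
the "05" suffix, the published lower bounds match a two-sided-95%
$z = 1.96$; a strict 5th percentile ($z = 1.645$) is available through the
`z` argument. In this simplified family $IC = \log_2 EBGM$ holds exactly,
and for all-positive tables $ROR>1 \iff PRR>1 \iff IC>0 \iff EBGM>1$; both
identities are property-tested.

**Zero cells.** When any cell is zero, 0.5 is added to all four cells
(Haldane–Anscombe) before any estimate, and the row is flagged. Since
signals require $n \ge 3$, the correction only matters for rare background
terms ($c = 0$).

**Signal rule.** A term is a signal when *all* of the following hold:
$n \ge 3$, ROR lower CI $> 1$, $PRR \ge 2$, $\chi^2 \ge 4$, $IC_{025} > 0$,
$EBGM_{05} > 2$. Every threshold is configurable via `signal_criteria()`,
and the output lists each violated clause. Ranked views sort by report
count ("frequency") or by $EBGM_{05}$ ("strength" — the lower-bound
ordering under which strong rare terms surface; the choice of strength key
is configurable since no single column is canonical). Outcome-like PTs
such as *Death* are retained as events by default, matching common
published practice; callers can exclude them by filtering terms.

## Time-to-onset

TTO is `EVENT_DT − START_DT` in days, computed only for target cases where
both dates have day precision; when several target-drug therapy rows carry
dates, the earliest start is used (earliest exposure as the onset origin).
Records with onset before start are excluded, and all exclusions are
counted by reason so that records + exclusions = target cases.

Quartiles use the inverted-ECDF convention with averaging
(`quantile(type = 2)`), under which quartiles are observed values — the
convention that yields IQR endpoints like 0 and 34 on heavily skewed onset
data. Latency bins are half-open: $[0,30), [30,180), [180,360), [360,720),
[720,\infty)$, so a 30-day onset falls in the second bin.

The Weibull fit maximizes the likelihood over $(\log\beta, \log\alpha)$
(shape, scale) with BFGS, using moment-based starting values on the
log-lifetime scale; Wald 95% intervals come from the observed information
on the log-parameters, so they are always positive and bracket the
estimates. Zero-day onsets are replaced by 0.5 day *in the likelihood
only* (Weibull support is strictly positive); they remain 0 in medians and
bins. Fits require at least 10 records and non-degenerate data. The hazard
pattern is classified from the shape CI: `early-failure` when the upper
bound is below 1, `wear-out` when the lower bound exceeds 1, `random`
otherwise.

## Descriptive summaries

Age bins (`<18, 18–44, 45–64, 65–75, >75` years) and weight bins
(`<50, 50–100, >100` kg) are left-closed on their printed labels — "65–75"
means $[65, 75)$ — the one convention under which the labels partition the
axis; both are configurable. Every summary carries an explicit `unknown`
bin, and percentages use the *sum of emitted counts* as denominator (so
they always total 100 up to rounding; published tables of this kind
sometimes quote a nominal case total that differs by a few reports from the
sum of their own rows). Outcomes are counted per *mention*: a case carrying
both death and hospitalization codes contributes to both rows, which is the
convention under which published outcome percentages are internally
consistent. The serious-outcome fraction is the share of death,
life-threatening, hospitalization and disability mentions among all outcome
mentions.

## The synthetic generator

`synth_config()` fixes the study conditions; `generate_reports()` emits
byte-identical files for identical config and seed. Defaults, chosen once:

* **500 target cases against a 20,000-case background.** The 40:1
  case/non-case asymmetry keeps the target's contribution to the total pair
  count modest — the regime in which relative reporting ratios behave like
  they do against a large database — while staying fast enough to
  regenerate inside every test run.
* **Five planted signals at relative risk 8–12** on PTs with baseline
  per-case reporting probabilities 0.01–0.06 (a 24-PT vocabulary across 9
  SOCs). Because injected signals inflate the target's total pair count,
  the *effective* PRR of a planted PT is its RR divided by that inflation
  (~2 here); RR 8–12 therefore lands planted effective ratios near 4–6,
  solidly above the signal thresholds without saturating them.
* **Reactions** are independent per-PT Bernoulli draws (target probability
  = baseline × RR, capped at 0.95), conditioned on at least one reaction by
  redrawing empty cases. Under that conditioning the expected count of PT
  *j* is exactly $n\,p_j / P(\ge 1 \text{ reaction})$, which the ground
  truth records — so recovery tests can use exact binomial bounds.
* **Onset latencies** are Weibull(shape 0.573, scale 38.653 days) — an
  early-failure pattern — truncated to whole days by `floor()`: an event
  occurring *T* days after the start date falls on the calendar date
  `start + floor(T)`, so same-day onsets yield 0-day intervals. Truncation
  is the calendar semantics of date differences and perturbs the recovered
  shape far less at sub-1 shapes than round-to-nearest does.
* **Missingness and versioning:** 15% of event dates missing or
  month-partial, 2% inconsistent (onset before start), 10% of cases emitted
  as two report versions differing only in receipt date and version number
  (so deduplication correctness is exactly checkable), 2% of background
  cases carrying the target drug concomitantly (exercising the PS-only
  rule). Demographics emulate an older, heavily missing COPD-like
  population (mean age 68, 43% unknown; 72% unknown weight; US/DE-dominated
  countries).

The generator does *not* emulate realistic database scale (tens of millions
of rows), drug co-reporting correlation structure, reporting-over-time
trends, or the true MedDRA vocabulary size. Passing recovery tests
therefore demonstrate the pipeline's correctness and statistical behaviour
under the stated model, not performance characteristics on real FAERS
extracts, where duplicate detection beyond case-id versioning and name
normalization beyond a synonym table may be needed.

## Problem sizes and numerical checks

The test suite regenerates all fixtures in code: unit fixtures use tens to
hundreds of cases; the planted-signal recovery test runs the full file
round trip at the default 500/20,000 scale; oracle equivalence compares all
four statistics against a naive transliteration of the formulas on 1,000
random tables at 1e-12 relative tolerance; Weibull recovery fits 200
replicates of 1,000 continuous draws (mean shape within 2% of truth, CI
coverage checked within [90%, 99%]) plus 50 replicates of day-truncated
data (median shape within 5%). `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

## Known limitations

Disproportionality measures are reporting associations, not incidence or
causality. The simplified EBGM (no shrinkage) overstates rare-term
disproportionality relative to a full MGPS posterior — the conjunction with
$n \ge 3$ and $EBGM_{05} > 2$ is what controls that. No multiple-testing
correction is applied, matching standard practice for these screening
criteria. The Weibull model conditions on observed onsets; it is not a
survival model and handles neither censoring nor competing risks
(Kaplan–Meier plots are intentionally out of scope). Probabilistic record
linkage across case identifiers is out of scope.
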