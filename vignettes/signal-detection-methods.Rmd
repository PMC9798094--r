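---
title: "Disproportionality signal detection for spontaneous reporting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reporting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spontaneous reporting systems (SRS) such as FAERS collect unsolicited
reports of adverse events (AEs) observed after drug exposure. Because
there is no denominator of exposed patients, association between a drug
and an event is assessed by *disproportionality*: is the event reported
with the drug more often than the database as a whole would predict?
`pvsignal` implements this pipeline end to end for FAERS-style
`$`-delimited quarterly tables, with a worked application to the five
triazole antifungal drugs (TADs: fluconazole, itraconazole,
voriconazole, posaconazole, isavuconazole), their important medical
event (IME) signal spectra, and a non-TAD antifungal comparator class.

# The statistics

All statistics derive from the report-level 2×2 table for a drug–event
pair: `a` reports with both, `b` with the drug and other events, `c`
with the event and other drugs, `d` with neither. With margins
`n_drug = a + b`, `n_event = a + c`, `n_total = a + b + c + d`, the
expected count under independence is

$$N_\mathrm{expected} = \frac{n_\mathrm{drug}\, n_\mathrm{event}}{n_\mathrm{total}}.$$

Two shrinkage-based measures share one observed/expected ratio:

$$\mathrm{ROR} = \frac{a + 0.5}{N_\mathrm{expected} + 0.5},
\qquad
\mathrm{IC} = \log_2 \mathrm{ROR} \;\text{(bits)}.$$

The additive 0.5 pulls small-count ratios toward 1, so rare pairs
cannot produce extreme values — the usual guard against spurious
associations at low expected frequency. By construction
`ic == log2(shrunk_ror)` exactly; the package asserts this identity in
its tests rather than computing the two quantities from separate
formulas.

Lower 95% bounds:

$$\mathrm{ROR}_{025} = \exp\!\Big(\ln \mathrm{ROR} - 1.96
  \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big),
\qquad
\mathrm{IC}_{025} = \mathrm{IC} - \frac{3.3}{\sqrt{a + 0.5}}
  - \frac{2}{(a + 0.5)^{3/2}}.$$

The IC penalty is the standard credibility-interval shrinkage
approximation: strictly positive, decaying as the observed count grows,
so `IC025 → IC` for large `a`.

A pair is a **significant signal** when `ROR025 > 1` with at least 3
reports, or `IC025 > 0` (both strict); a **strong signal** additionally
has `IC025 > 4`. All thresholds are arguments with these defaults.

## Numerical and policy choices

* **Zero cells.** The ROR variance term uses the classical `1/a + 1/b +
  1/c + 1/d`, which is undefined when any cell is zero. The bound is
  then reported as missing rather than Haldane-corrected: the 0.5
  shrinkage belongs to the *ratio*, not the variance. The IC remains
  defined, so such pairs can still signal through the IC path — which is
  also why the decision rule is a disjunction.
* **Interval centring.** The point estimate is the shrunk ROR but the
  standard error is the classical 2×2 log-odds one. By default the
  interval is centred on `ln(shrunk ROR)`, as the formulas read
  together; `ror_lower_bound(center = "crude")` offers the classical
  `ad/bc` centring for sensitivity analysis. On real TAD data the two
  differ visibly only for small or very unbalanced tables.
* **Counting unit.** A report counts at most once per (drug, event)
  pair regardless of how often a PT is listed, and once per SOC however
  many of its PTs map there. This is the "number of reports" semantics
  of the 2×2 table.
* **Two backgrounds.** `"all-other-drugs"` splits the whole universe at
  the target drug. `"comparator-class"` first restricts the universe to
  reports whose suspect drug is the target or a comparator-class member
  (for the TAD study: amphotericin B, echinocandins, flucytosine,
  terbinafine), so the other target drugs leave the background
  entirely. When comparators carry the same events — e.g. fungal
  infections reflecting the treated population rather than the drug —
  the class background absorbs that shared risk and IC025 values drop;
  the package tests this direction on constructed scenarios.

# Preprocessing

FAERS cases accumulate submissions. The pipeline keeps, per `caseid`,
the submission with the latest `fda_dt`; ties are broken by the largest
`primaryid` (the latest submission sequence) — some deterministic
tie-break is required for reproducibility, and later sequence numbers
are the natural choice. Quality rules then remove reports with
harmonized age above 150 years (strict inequality; ages arrive with a
unit code — decades, years, months, weeks, days, hours — and are
converted to years *before* filtering, otherwise an age rule is
meaningless), cases whose submissions disagree on sex (`unknown` never
conflicts; the whole case is removed), and reports dated before the
analysis window start (default 2012-10-01, configurable). Every removal
is logged per rule in an attrition table, and the tests require the
logged counts to reconcile exactly with input minus output.

Analysis is restricted to reports with at least one primary-suspect
(`PS`) drug mention; the suspect set of a report comes from those
mentions only, while all mentions remain available for comedication
counting.

# Vocabulary

MedDRA and the EMA IME list are licensed and cannot ship with an open
package. `pvsignal` therefore bundles a *mock* vocabulary — 200+ PTs
spanning the 27 SOCs used in the TAD case study, with an IME subset of
roughly half, plus synonym dictionaries for the TADs and the comparator
antifungals — and reads user-supplied real vocabularies from the same
three CSV layouts (`synonyms.csv`, `pt_soc.csv`, `ime.csv`). Lookups
are case-, whitespace- and punctuation-insensitive; unmapped PTs route
to an explicit `UNMAPPED` SOC and never error. Vocabulary version drift
is real (PT↔SOC assignments move between MedDRA versions); the bundle
records its source in metadata but does not attempt to resolve
versions.

Two serious-outcome definitions coexist as named predicates, because
published tallies use both: `strict4` (Death, Life-Threatening,
Disability, Hospitalization) and `nonhosp5` (Death, Life-Threatening,
Disability, Congenital Anomaly, Required Intervention — the
five-category sum behind headline "serious outcome" counts). Neither is
silently preferred; `serious_outcome_count()` takes the definition by
name.

# The synthetic generator

Real FAERS extracts cannot ship either, so every stage is validated on
synthetic data with known ground truth (`synthetic_scenario()`,
`generate_faers()`). The generative model:

* a suspect drug per report from a prevalence vector (default shape: 5
  TAD targets at 2%, 4 comparators at 1.5%, 40 background drugs);
* a comedication count from a decaying distribution, with the named
  drugs drawn distinctly per report;
* independent event inclusion per (drug, event) with probability
  `min(1, λ · baseline · (1 + slope · m))` for IME events, where `λ` is
  the planted multiplier (`λ = 1` plants nothing), `baseline` defaults
  to 1%, and `slope` (default 5% per added comedication) produces the
  polypharmacy-dependent IME risk the comedication analysis must
  recover;
* a report whose draws all miss receives one nonspecific *filler* PT
  outside the scored event list, so every report has a reaction but
  scored-event margins stay exactly binomial;
* outcome codes drawn per category, conditional on IME presence;
* duplicates (an extra, earlier submission) and quality defects
  (age > 150, conflicting-sex submission, pre-window date) injected on
  disjoint sampled subsets, so the truth record states the exact
  expected attrition at every stage.

`expected_ic()` returns the analytic expectation of the IC for a pair,
accounting for the comedication mixture and for the target drug's own
contribution to the event margin — for a rare drug this approaches
`log2(λ)`, and the tests verify both the limiting cases and agreement
with simulation to within 0.1 bit at 10^6 reports.

What the generator does *not* emulate: free-text misspellings beyond
synonym/case/whitespace variants, reporting-rate secular trends,
correlated event clusters within reports, and country-specific coding
habits. Passing tests therefore demonstrate that the *pipeline*
recovers what it is pointed at, not that real FAERS data are this
clean; on real data, dedup rates and unmapped-term counts must be
inspected via the attrition log and vocabulary counters.

## Problem sizes used in validation

The planted-recovery suite uses 20 replicates of 10^5 reports (49
drugs, 50 IME events, twelve pairs at λ = 4) and requires ≥ 95%
recovery with ≤ 5% false positives on null pairs; observed recovery is
100% with false-positive rates around 1–2%, driven by the shrinkage
penalty. IC convergence is checked at a single 10^6-report run. Null
calibration (no planted pairs, 50×50 grid at 10^5 reports) keeps the
IC-path flag rate well under 5%. These sizes give stable proportions
while keeping the whole suite in the low minutes on one CPU.

# Reproducing the printed-table arithmetic

The package ships the published cohort tallies of the TAD case study
(drug-wise AE/IME counts, outcome categories, and the outcome-by-PT
cross-tab of the four common significant signals — cholestasis,
drug-induced liver injury, QT interval prolongation, renal impairment)
as plain CSV reference data. The tabulation functions reproduce the
printed percentages from these counts with half-up 2-decimal rounding:
the 54.21% IME share, the 21.83%/34.51% death percentages, the 2,357
five-category serious-outcome sum, and the 4.13% renal-impairment death
cell over the 484-record grand total. One printed value does not follow
from its own table's counts: the voriconazole IME share prints as
42.65% where 2372/5563 gives 42.64%; the package reports the
count-derived value and checks agreement at printed precision.

# Known limitations

* Disproportionality quantifies reporting association, not causality or
  incidence; no multiple-testing correction is applied, matching
  standard SRS practice — spectra are screening output.
* Probabilistic record linkage across different `caseid`s is out of
  scope; deduplication is rule-based within a case.
* The comparator-class background is only as good as the class
  membership list supplied.
* The shipped vocabulary is a mock; real analyses should mount licensed
  MedDRA/IME tables in the documented CSV formats.
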