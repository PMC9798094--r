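# pvsignal

Disproportionality-based signal detection for FAERS-style spontaneous
adverse-event reporting data.

Spontaneous reporting systems have no exposure denominator, so
drug–event associations are screened by asking whether an event is
reported with a drug more often than the database predicts. `pvsignal`
implements that pipeline end to end:

* **Ingestion** of FAERS-dialect quarterly ASCII tables (DEMO, DRUG,
  REAC, OUTC, THER, INDI; `$`-delimited, one header line), with
  malformed rows counted rather than silently dropped.
* **Preprocessing**: case deduplication (latest `fda_dt` per `caseid`,
  largest `primaryid` on ties), quality filters (age > 150 after unit
  harmonization, conflicting-sex cases, pre-window dates), restriction
  to primary-suspect (`PS`) drug mentions, with a reconciled attrition
  log.
* **Vocabulary**: synonym-dictionary drug normalization and
  MedDRA-style PT → SOC / IME mapping. A mock vocabulary (200+ PTs, 27
  SOCs, ~half IME) ships in `inst/extdata`; licensed MedDRA/EMA-IME
  tables mount via the same CSV layouts.
* **Statistics**: shrinkage disproportionality with a shared ratio,

  ```
  N_expected = n_drug * n_event / n_total
  ROR   = (a + 0.5) / (N_expected + 0.5)        IC = log2(ROR)  [bits]
  ROR025 = exp(ln ROR − 1.96·sqrt(1/a + 1/b + 1/c + 1/d))
  IC025  = IC − 3.3·(a + 0.5)^(−1/2) − 2·(a + 0.5)^(−3/2)
  ```

  A *significant* signal has `ROR025 > 1` with ≥ 3 cases or
  `IC025 > 0`; a *strong* signal additionally has `IC025 > 4`.
* **Spectra and cohort tables**: SOC-level dual AE/IME analysis,
  PT-level IME signal spectra under two backgrounds (all other drugs,
  or a comparator drug class), heatmap rendering, cohort demographics,
  drug-wise shares, comedication-bin IME incidence, and outcome
  cross-tabs.
* **Synthetic data**: a FAERS-like generator with planted drug–event
  multipliers, injected duplicates/defects and an analytic expected-IC,
  so the whole pipeline is testable without any FAERS download.

The worked case study is the triazole antifungal class (fluconazole,
itraconazole, voriconazole, posaconazole, isavuconazole) against a
non-TAD antifungal comparator class.

## Worked example

Generate a synthetic universe with four planted associations, run the
pipeline, and read the IME spectrum:

```r
library(pvsignal)

bundle  <- load_vocabulary()
planted <- tibble::tibble(
  drug   = c("voriconazole", "voriconazole", "fluconazole", "posaconazole"),
  pt     = c("Cholestasis", "Hallucination", "QT interval prolonged",
             "Drug-induced liver injury"),
  lambda = c(6, 4, 5, 4))
scenario <- default_scenario(n_reports = 20000, bundle = bundle,
                             planted = planted, seed = 7)
gen <- generate_faers(scenario, seed = 7)
sr  <- preprocess_reports(gen$tables, bundle)
spec <- ime_spectrum(sr, bundle, drugs_in_class(bundle, "TAD"))
subset(spec, significant,
       select = c(drug, event, a, n_expected, ror025, ic, ic025))
```

```
           drug                     event  a n_expected ror025   ic  ic025
1   fluconazole     QT interval prolonged 28       4.18   4.04 2.61  1.977
3  posaconazole Drug-induced liver injury 17       3.92   2.38 1.99  1.170
7  voriconazole               Cholestasis 29       4.05   4.33 2.70  2.077
8  voriconazole             Hallucination 17       3.75   2.48 2.04  1.225
...
```

All four planted pairs surface: e.g. voriconazole–cholestasis is
observed 29 times against 4.05 expected, giving `IC = 2.70` bits with a
lower bound of `2.08` — a significant signal (and the remaining rows
show the borderline companions a screening method is expected to
produce). The attrition log reconciles exactly with the generator's
truth record (`gen$truth`): 500 duplicate submissions removed, then
100 + 100 + 200 reports by the three quality rules:

```r
attrition_log(sr)
#>   stage          rule                                       n_removed n_out
#> 1 raw            demo rows without caseid/primaryid                 0 20000
#> 2 dedup          duplicate submissions (latest fda_dt kept)       500 20000
#> 3 quality_filter age > 150                                        100    NA
#> 4 quality_filter sex conflict across submissions                  100    NA
#> 5 quality_filter fda_dt outside analysis window                   200 19600
#> 6 restrict_role  no drug mention with role PS                       0 19600
```

`demo_run(seed = 7)` wraps the same flow and writes every artifact
(attrition, SOC tables, spectra + heatmaps, cohort summaries,
comedication grid, outcome cross-tab) to a directory.

## Vocabulary CSV formats

| file | columns | meaning |
|---|---|---|
| `synonyms.csv` | `raw_name,canonical,class` | reported name → canonical drug id, with class tag |
| `pt_soc.csv` | `pt,soc` | preferred term → primary system organ class |
| `ime.csv` | `pt` | PTs designated important medical events |

Strict UTF-8; lookups ignore case, whitespace and punctuation. See the
methods vignette (`vignettes/signal-detection-methods.Rmd`) for the
model details, design choices and limitations.
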