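# Descriptive cohort tabulation: demographics, report years, reporter
# countries, clinical outcomes, drug-wise shares, comedication-bin IME
# incidence, and the outcome-by-PT cross-tabulation for selected
# significant signals. All percentages are count/total*100 rounded
# half-up to 2 decimals.

age_band_breaks <- c(0, 18, 60, 75, 90, Inf)
age_band_labels <- c("0-17", "18-59", "60-74", "75-89", ">=90")

#' Summarize a report cohort
#'
#' Tabulates sex, age bands (under 18, 18--59, 60--74, 75--89, 90+,
#' unknown), median and interquartile age, calendar year, reporter
#' country (largest four, rest pooled) and clinical outcome categories.
#' Outcome percentages can sum above 100 because one report may carry
#' several outcomes; every other partition sums to the cohort total.
#'
#' @param sr a preprocessed `safety_reports` object.
#' @param bundle a [vocabulary_bundle()].
#' @param cohort `"AE"` (all reports) or `"IME"` (reports with at least
#'   one IME-designated PT).
#' @param n_countries number of countries listed individually.
#' @return an object of class `cohort_summary`.
#' @export
summarize_cohort <- function(sr, bundle, cohort = c("AE", "IME"),
                             n_countries = 4) {
  cohort <- match.arg(cohort)
  cases <- sr$cases
  if (cohort == "IME") {
    ime_ids <- ime_report_ids(sr, bundle)
    cases <- dplyr::filter(cases, .data$caseid %in% ime_ids)
  }
  total <- nrow(cases)
  if (!total) rlang::warn("empty cohort: all-zero summary")
  strat <- function(x, levels) {
    x <- factor(x, levels = levels)
    tibble::tibble(stratum = levels,
                   n = as.integer(table(x)),
                   pct = if (total) pct2(as.integer(table(x)), total) else 0)
  }

  sex_tbl <- strat(cases$sex, c("M", "F", "unknown"))

  band <- cut(cases$age_years, breaks = age_band_breaks,
              labels = age_band_labels, right = FALSE)
  band <- as.character(band)
  band[is.na(band)] <- "unknown"
  age_tbl <- strat(band, c(age_band_labels, "unknown"))

  year_tbl <- cases |>
    dplyr::filter(!is.na(.data$year)) |>
    dplyr::count(.data$year, name = "n") |>
    dplyr::mutate(pct = pct2(.data$n, total)) |>
    dplyr::rename(stratum = "year")

  country <- dplyr::coalesce(cases$reporter_country, "unknown")
  top <- names(sort(table(country), decreasing = TRUE))
  top <- utils::head(top, n_countries)
  country[!country %in% top] <- "Other countries"
  country_tbl <- country |>
    table() |>
    sort(decreasing = TRUE) |>
    (\(x) tibble::tibble(stratum = names(x), n = as.integer(x),
                         pct = pct2(as.integer(x), total)))()

  report_outcomes <- sr$outcomes |>
    dplyr::filter(.data$caseid %in% cases$caseid) |>
    dplyr::distinct(.data$caseid, .data$outc_cod)
  map <- bundle$outcome_map
  outcome_tbl <- tibble::tibble(code = names(map), label = unname(map)) |>
    dplyr::left_join(dplyr::count(report_outcomes, .data$outc_cod, name = "n"),
                     by = c(code = "outc_cod")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  pct = if (total) pct2(.data$n, total) else 0)

  known_age <- cases$age_years[!is.na(cases$age_years)]
  structure(list(
    cohort = cohort,
    total = total,
    sex = sex_tbl,
    age_bands = age_tbl,
    age_median = if (length(known_age)) stats::median(known_age) else NA_real_,
    age_iqr = if (length(known_age)) {
      unname(stats::quantile(known_age, c(0.25, 0.75)))
    } else c(NA_real_, NA_real_),
    years = year_tbl,
    countries = country_tbl,
    outcomes = outcome_tbl,
    report_outcomes = report_outcomes
  ), class = "cohort_summary")
}

# caseids with >= 1 IME-designated PT
ime_report_ids <- function(sr, bundle) {
  keep <- norm_key(sr$reactions$pt) %in% bundle$ime_set
  unique(sr$reactions$caseid[keep])
}

#' Build a cohort summary from printed marginal tallies
#'
#' For reproducing arithmetic on published summary tables where only the
#' per-category outcome counts (not per-report outcome sets) are
#' available.
#'
#' @param total cohort size.
#' @param outcome_counts named integer vector, outcome code -> count.
#' @return a `cohort_summary` with only totals and outcome marginals.
#' @export
cohort_summary_from_counts <- function(total, outcome_counts) {
  map <- outcome_code_map()
  codes <- names(outcome_counts)
  stopifnot(all(codes %in% names(map)))
  structure(list(
    cohort = NA_character_,
    total = total,
    outcomes = tibble::tibble(code = codes, label = unname(map[codes]),
                              n = as.integer(outcome_counts),
                              pct = pct2(as.integer(outcome_counts), total)),
    report_outcomes = NULL
  ), class = "cohort_summary")
}

#' Count serious outcomes in a cohort
#'
#' With per-report outcome sets available (a summary from
#' [summarize_cohort()]), counts each report once whose outcome set
#' intersects the definition's categories. For a summary built from
#' printed marginal tallies ([cohort_summary_from_counts()]) the
#' category counts are summed instead — an upper bound on the distinct-
#' report count, and the arithmetic used in published headline figures.
#'
#' @param summary a `cohort_summary`.
#' @param definition `"strict4"` (Death, Life-Threatening, Disability,
#'   Hospitalization) or `"nonhosp5"` (Death, Life-Threatening,
#'   Disability, Congenital Anomaly, Required Intervention).
#' @return integer count.
#' @export
serious_outcome_count <- function(summary, definition = "strict4") {
  codes <- serious_definition(definition)
  if (!is.null(summary$report_outcomes)) {
    hits <- summary$report_outcomes |>
      dplyr::filter(.data$outc_cod %in% codes)
    return(dplyr::n_distinct(hits$caseid))
  }
  sum(summary$outcomes$n[summary$outcomes$code %in% codes])
}

#' Per-drug AE and IME shares
#'
#' One row per target drug with report counts and percentages of the AE
#' cohort (reports naming the drug as suspect) and of the IME cohort
#' (the subset with at least one IME PT). Denominators are the numbers
#' of distinct reports naming any target drug, so a report with two
#' target suspects counts in both drug rows.
#'
#' @inheritParams summarize_cohort
#' @param drugs canonical target drug ids.
#' @return tibble with columns `drug`, `n_ae`, `pct_ae`, `n_ime`,
#'   `pct_ime`.
#' @export
drugwise_share <- function(sr, bundle, drugs) {
  sus <- dplyr::filter(sr$suspects, .data$drug %in% drugs)
  ime_ids <- ime_report_ids(sr, bundle)
  total_ae <- dplyr::n_distinct(sus$caseid)
  total_ime <- dplyr::n_distinct(intersect(sus$caseid, ime_ids))
  out <- tibble::tibble(drug = drugs) |>
    dplyr::left_join(dplyr::count(sus, .data$drug, name = "n_ae"), by = "drug") |>
    dplyr::left_join(
      sus |> dplyr::filter(.data$caseid %in% ime_ids) |>
        dplyr::count(.data$drug, name = "n_ime"),
      by = "drug") |>
    dplyr::mutate(
      n_ae = dplyr::coalesce(.data$n_ae, 0L),
      n_ime = dplyr::coalesce(.data$n_ime, 0L),
      pct_ae = if (total_ae) pct2(.data$n_ae, total_ae) else 0,
      pct_ime = if (total_ime) pct2(.data$n_ime, total_ime) else 0
    ) |>
    dplyr::relocate("drug", "n_ae", "pct_ae", "n_ime", "pct_ime")
  attr(out, "total_ae") <- total_ae
  attr(out, "total_ime") <- total_ime
  out
}

#' Share table from printed counts
#'
#' @param n named counts.
#' @param total denominator.
#' @return tibble with `key`, `n`, `pct` (2-decimal, half-up).
#' @export
share_table <- function(n, total) {
  tibble::tibble(key = names(n), n = as.integer(n),
                 pct = pct2(as.integer(n), total))
}

#' IME incidence by comedication count
#'
#' For each target drug, bins its reports by the number of distinct
#' non-target drugs mentioned in the report (any role): 0, 1, ..., 5 and
#' `>5`. Within each bin, incidence is the percentage of reports that
#' carry at least one IME PT. Bins partition each drug's reports.
#'
#' @inheritParams drugwise_share
#' @return tibble of class `comedication_grid` with columns `drug`,
#'   `bin`, `n_ae`, `n_ime`, `incidence` (`NA` for empty bins).
#' @export
comedication_incidence <- function(sr, bundle, drugs) {
  bins <- c(as.character(0:5), ">5")
  ime_ids <- ime_report_ids(sr, bundle)
  rows <- lapply(drugs, function(d) {
    ids <- sr$suspects$caseid[sr$suspects$drug == d]
    if (!length(ids)) {
      return(tibble::tibble(drug = d, bin = bins, n_ae = 0L, n_ime = 0L,
                            incidence = NA_real_))
    }
    comed <- sr$drugs |>
      dplyr::filter(.data$caseid %in% ids, !is.na(.data$drug),
                    .data$drug != d) |>
      dplyr::distinct(.data$caseid, .data$drug) |>
      dplyr::count(.data$caseid, name = "m")
    per_case <- tibble::tibble(caseid = ids) |>
      dplyr::left_join(comed, by = "caseid") |>
      dplyr::mutate(
        m = dplyr::coalesce(.data$m, 0L),
        bin = ifelse(.data$m > 5, ">5", as.character(.data$m)),
        ime = .data$caseid %in% ime_ids
      )
    per_case |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n_ae = dplyr::n(), n_ime = sum(.data$ime),
                       .groups = "drop") |>
      (\(x) dplyr::left_join(tibble::tibble(drug = d, bin = bins), x,
                             by = "bin"))() |>
      dplyr::mutate(
        n_ae = dplyr::coalesce(.data$n_ae, 0L),
        n_ime = as.integer(dplyr::coalesce(.data$n_ime, 0L)),
        incidence = ifelse(.data$n_ae > 0, pct2(.data$n_ime, .data$n_ae),
                           NA_real_)
      )
  })
  out <- dplyr::bind_rows(rows)
  out$bin <- factor(out$bin, levels = bins)
  class(out) <- c("comedication_grid", class(tibble::tibble()))
  out
}

#' Render a comedication-incidence grid as a color-scale plot
#'
#' @param grid a `comedication_grid` from [comedication_incidence()].
#' @param file optional output path for the figure.
#' @return a ggplot object.
#' @export
render_comedication <- function(grid, file = NULL) {
  fig <- ggplot2::ggplot(
    dplyr::filter(grid, !is.na(.data$incidence)),
    ggplot2::aes(x = .data$bin, y = .data$drug, fill = .data$incidence)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%%", .data$incidence)), size = 2.8) +
    ggplot2::scale_fill_gradient(low = "steelblue", high = "firebrick",
                                 name = "IME incidence (%)") +
    ggplot2::labs(x = "Number of comedications", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(file)) ggplot2::ggsave(file, fig, width = 6, height = 3, dpi = 150)
  fig
}

#' Outcome-by-PT cross-tabulation for selected signals
#'
#' For reports carrying any of the target PTs, counts outcome records as
#' (report, outcome category, PT) triples and expresses each cell as a
#' percentage of the grand total of records across all categories —
#' including the pooled non-listed categories — so cells are comparable
#' across outcome severities.
#'
#' @inheritParams drugwise_share
#' @param target_pts PTs to cross-tabulate; default the four common
#'   significant signals (cholestasis, drug-induced liver injury, QT
#'   interval prolongation, renal impairment).
#' @param listed outcome codes listed individually; the rest are pooled
#'   as `"(unlisted)"`.
#' @return tibble with `outcome`, `pt`, `records`, `pct`; attributes
#'   `grand_total` and `listed_total`.
#' @export
significant_ime_outcomes <- function(sr, bundle,
                                     target_pts = c(
                                       "Cholestasis",
                                       "Drug-induced liver injury",
                                       "QT interval prolonged",
                                       "Renal impairment"),
                                     listed = c("DE", "LT", "HO", "DS", "RI")) {
  keys <- norm_key(target_pts)
  hits <- sr$reactions |>
    dplyr::mutate(key = norm_key(.data$pt)) |>
    dplyr::filter(.data$key %in% keys) |>
    dplyr::mutate(pt = target_pts[match(.data$key, keys)]) |>
    dplyr::distinct(.data$caseid, .data$pt)
  records <- dplyr::inner_join(hits, sr$outcomes, by = "caseid",
                               relationship = "many-to-many") |>
    dplyr::distinct(.data$caseid, .data$pt, .data$outc_cod)
  grand_total <- nrow(records)
  records$group <- ifelse(records$outc_cod %in% listed,
                          records$outc_cod, "(unlisted)")
  cells <- records |>
    dplyr::count(.data$group, .data$pt, name = "records") |>
    dplyr::rename(outcome = "group")
  cells$pt[cells$outcome == "(unlisted)"] <- "(all)"
  cells <- cells |>
    dplyr::group_by(.data$outcome, .data$pt) |>
    dplyr::summarise(records = sum(.data$records), .groups = "drop")
  out <- crosstab_percentages(cells)
  attr(out, "listed_total") <-
    sum(out$records[out$outcome %in% listed])
  out
}

#' Percentages over the grand total of a cross-tab
#'
#' Adds a `pct` column (2-decimal, half-up) over the sum of the
#' `records` column; used both on pipeline output and on printed
#' cross-tabs.
#'
#' @param cells tibble with columns `outcome`, `pt`, `records`.
#' @return the tibble with `pct` added; attribute `grand_total`.
#' @export
crosstab_percentages <- function(cells) {
  grand <- sum(cells$records)
  out <- dplyr::mutate(cells, pct = pct2(.data$records, grand))
  attr(out, "grand_total") <- grand
  out
}

#' Reference tallies for the triazole antifungal case study
#'
#' Published summary tallies (drug-wise AE/IME counts and outcome
#' category counts for the AE and IME cohorts, plus the outcome-by-PT
#' cross-tab of the four common significant signals) shipped as package
#' data; used to exercise the tabulation arithmetic on a real cohort's
#' printed margins.
#'
#' @return list with tibbles `cohort` (section, key, ae, ime) and
#'   `crosstab` (outcome, pt, records).
#' @export
tad_reference_tallies <- function() {
  dir <- system.file("extdata", package = "pvsignal")
  list(
    cohort = readr::read_csv(file.path(dir, "tad_cohort_tallies.csv"),
                             col_types = "ccii", progress = FALSE),
    crosstab = readr::read_csv(file.path(dir, "tad_outcome_crosstab.csv"),
                               col_types = "cci", progress = FALSE)
  )
}
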