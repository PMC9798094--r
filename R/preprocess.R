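# Case-level preprocessing: raw quarterly tables -> one deduplicated,
# quality-filtered collection of safety reports restricted to a drug
# role code. Every removal is accounted for in an attrition log.

#' Build a safety-report collection from raw tables
#'
#' Joins the children tables (DRUG, REAC, OUTC) to DEMO by `primaryid`,
#' validates the join (children rows whose `primaryid` has no DEMO row
#' are dropped and counted), and rejects DEMO rows without a `caseid`.
#' The result still holds one row per *submission*; run [deduplicate()]
#' next to collapse to one row per case.
#'
#' @param raw a `faers_tables` object from [read_faers_quarter()] or
#'   [generate_faers()].
#' @return an object of class `safety_reports`.
#' @export
as_safety_reports <- function(raw) {
  demo <- raw$demo
  no_case <- is.na(demo$caseid) | is.na(demo$primaryid)
  rejected <- sum(no_case)
  demo <- demo[!no_case, , drop = FALSE]
  cases <- tibble::tibble(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    fda_dt = demo$fda_dt_iso,
    fda_dt_num = demo$fda_dt_num,
    fda_dt_precision = demo$fda_dt_precision,
    year = suppressWarnings(as.integer(substr(demo$fda_dt_iso, 1, 4))),
    sex = demo$sex,
    age_years = demo$age_years,
    reporter_country = demo$reporter_country
  )
  id_map <- dplyr::distinct(cases, .data$primaryid, .data$caseid)
  join_child <- function(df) {
    df <- dplyr::inner_join(df, id_map, by = "primaryid")
    df
  }
  orphans <- vapply(c("drug", "reac", "outc"), function(tab) {
    nrow(raw[[tab]]) - sum(raw[[tab]]$primaryid %in% id_map$primaryid)
  }, numeric(1))
  drugs <- join_child(raw$drug)
  reactions <- join_child(raw$reac) |>
    dplyr::filter(!is.na(.data$pt)) |>
    dplyr::distinct(.data$primaryid, .data$caseid, .data$pt)
  outcomes <- join_child(raw$outc) |>
    dplyr::filter(!is.na(.data$outc_cod)) |>
    dplyr::distinct(.data$primaryid, .data$caseid, .data$outc_cod)

  structure(list(
    cases = cases,
    drugs = drugs,
    reactions = reactions,
    outcomes = outcomes,
    submissions = NULL,
    dedup_done = FALSE,
    role = NA_character_,
    attrition = tibble::tibble(
      stage = "raw", rule = "demo rows without caseid/primaryid",
      n_removed = rejected, n_out = dplyr::n_distinct(cases$caseid)
    ),
    log = list(orphan_child_rows = orphans)
  ), class = "safety_reports")
}

#' Deduplicate submissions to one report per case
#'
#' FAERS cases accumulate submissions; within a `caseid` the submission
#' with the latest `fda_dt` is kept. Among submissions tied on
#' (`caseid`, `fda_dt`) the numerically largest `primaryid` (the latest
#' submission sequence) wins, a deterministic tie-break. A submission
#' with a missing `fda_dt` loses to any dated one. Idempotent.
#'
#' @param sr a `safety_reports` object.
#' @return `sr` with one case row per `caseid`; the pre-dedup submission
#'   table is retained for the later sex-conflict check.
#' @export
deduplicate <- function(sr) {
  stopifnot(inherits(sr, "safety_reports"))
  submissions <- if (sr$dedup_done) sr$submissions else sr$cases
  n_in <- nrow(sr$cases)
  keep <- submissions |>
    dplyr::mutate(
      .date_key = dplyr::coalesce(.data$fda_dt_num, -1L),
      .pid_key = suppressWarnings(as.numeric(.data$primaryid))
    ) |>
    dplyr::arrange(.data$caseid, dplyr::desc(.data$.date_key),
                   dplyr::desc(.data$.pid_key)) |>
    dplyr::distinct(.data$caseid, .keep_all = TRUE) |>
    dplyr::select(-dplyr::all_of(c(".date_key", ".pid_key")))
  kept_pid <- keep$primaryid
  sr$cases <- keep
  sr$drugs <- dplyr::filter(sr$drugs, .data$primaryid %in% kept_pid)
  sr$reactions <- dplyr::filter(sr$reactions, .data$primaryid %in% kept_pid)
  sr$outcomes <- dplyr::filter(sr$outcomes, .data$primaryid %in% kept_pid)
  sr$submissions <- submissions
  sr$dedup_done <- TRUE
  sr$attrition <- dplyr::bind_rows(sr$attrition, tibble::tibble(
    stage = "dedup", rule = "duplicate submissions (latest fda_dt kept)",
    n_removed = n_in - nrow(keep), n_out = nrow(keep)
  ))
  sr
}

#' Quality-filter deduplicated reports
#'
#' Three removal rules, applied in order and each logged separately:
#' reports with harmonized age above 150 years; cases whose submissions
#' disagree on sex (evaluated across all pre-dedup submissions of the
#' case; `unknown` never conflicts); reports whose `fda_dt` falls before
#' the analysis window start (default 2012-10-01) or after an optional
#' window end. Reports with a missing age or date are never removed by
#' the corresponding rule.
#'
#' @param sr a deduplicated `safety_reports` object.
#' @param window_start ISO date string; reports before it are removed.
#' @param window_end optional ISO date string.
#' @param max_age age cutoff in years; strictly greater is removed.
#' @return filtered `safety_reports` with per-rule attrition rows.
#' @export
quality_filter <- function(sr, window_start = "2012-10-01",
                           window_end = NULL, max_age = 150) {
  stopifnot(inherits(sr, "safety_reports"))
  if (!sr$dedup_done) {
    stop_pv("quality_filter() requires deduplicate() first: the sex-conflict ",
            "rule is evaluated across all submissions of a case")
  }
  cases <- sr$cases

  rule_age <- !is.na(cases$age_years) & cases$age_years > max_age
  conflicted <- sr$submissions |>
    dplyr::filter(.data$sex %in% c("M", "F")) |>
    dplyr::distinct(.data$caseid, .data$sex) |>
    dplyr::count(.data$caseid) |>
    dplyr::filter(.data$n > 1L)
  rule_sex <- cases$caseid %in% conflicted$caseid & !rule_age
  start_num <- iso_to_num(window_start)
  rule_window <- !is.na(cases$fda_dt_num) & cases$fda_dt_num < start_num &
    !rule_age & !rule_sex
  if (!is.null(window_end)) {
    end_num <- iso_to_num(window_end)
    rule_window <- rule_window |
      (!is.na(cases$fda_dt_num) & cases$fda_dt_num > end_num &
         !rule_age & !rule_sex)
  }

  drop <- rule_age | rule_sex | rule_window
  kept <- cases[!drop, , drop = FALSE]
  sr$cases <- kept
  sr$drugs <- dplyr::filter(sr$drugs, .data$caseid %in% kept$caseid)
  sr$reactions <- dplyr::filter(sr$reactions, .data$caseid %in% kept$caseid)
  sr$outcomes <- dplyr::filter(sr$outcomes, .data$caseid %in% kept$caseid)
  sr$attrition <- dplyr::bind_rows(sr$attrition, tibble::tibble(
    stage = "quality_filter",
    rule = c(paste0("age > ", max_age), "sex conflict across submissions",
             "fda_dt outside analysis window"),
    n_removed = c(sum(rule_age), sum(rule_sex), sum(rule_window)),
    n_out = c(NA_integer_, NA_integer_, nrow(kept))
  ))
  sr
}

#' Normalize the drug mentions of a report collection
#'
#' Adds a `drug` column to the mention table: the canonical id from the
#' synonym dictionary, matched against the reported `drugname` and then
#' the active-ingredient string (`prod_ai`); mentions matching neither
#' fall back to the normalized raw name so that unknown drugs still have
#' a stable identity in the background. The count of unmatched mentions
#' is logged.
#'
#' @param sr a `safety_reports` object.
#' @param bundle a [vocabulary_bundle()].
#' @return `sr` with normalized drug identities.
#' @export
normalize_report_drugs <- function(sr, bundle) {
  stopifnot(inherits(sr, "safety_reports"))
  d <- sr$drugs
  canon <- dplyr::coalesce(
    normalize_drug(d$drugname, bundle),
    normalize_drug(d$prod_ai, bundle)
  )
  # fallback identity: lowercased alphanumeric key, matching the style
  # of canonical ids so unknown drugs are scannable by that key
  fallback <- tolower(norm_key(dplyr::coalesce(d$drugname, d$prod_ai, "")))
  fallback[fallback == ""] <- NA_character_
  d$drug <- dplyr::coalesce(canon, fallback)
  d$drug_matched <- !is.na(canon)
  sr$drugs <- d
  sr$log$unmatched_drug_mentions <- sum(!d$drug_matched & !is.na(d$drug))
  sr
}

#' Restrict reports to a drug role code
#'
#' Keeps reports carrying at least one drug mention with the given role
#' (default `PS`, primary suspect) and populates the per-report suspect
#' drug set from those mentions only. Other mentions remain available
#' for comedication counting.
#'
#' @param sr a `safety_reports` object with normalized drugs.
#' @param role one of `"PS"`, `"SS"`, `"C"`, `"I"`.
#' @return `sr` with a `suspects` table (`caseid`, `drug`) and filtered
#'   cases.
#' @export
restrict_role <- function(sr, role = "PS") {
  stopifnot(inherits(sr, "safety_reports"))
  if (!role %in% c("PS", "SS", "C", "I")) {
    stop_pv("unknown role code: ", role, " (expected PS, SS, C or I)")
  }
  if (!"drug" %in% names(sr$drugs)) {
    stop_pv("drug mentions are not normalized; run normalize_report_drugs()")
  }
  n_in <- nrow(sr$cases)
  suspects <- sr$drugs |>
    dplyr::filter(.data$role_cod == role, !is.na(.data$drug)) |>
    dplyr::distinct(.data$caseid, .data$drug)
  kept_ids <- unique(suspects$caseid)
  sr$cases <- dplyr::filter(sr$cases, .data$caseid %in% kept_ids)
  sr$drugs <- dplyr::filter(sr$drugs, .data$caseid %in% kept_ids)
  sr$reactions <- dplyr::filter(sr$reactions, .data$caseid %in% kept_ids)
  sr$outcomes <- dplyr::filter(sr$outcomes, .data$caseid %in% kept_ids)
  sr$suspects <- suspects
  sr$role <- role
  sr$attrition <- dplyr::bind_rows(sr$attrition, tibble::tibble(
    stage = "restrict_role",
    rule = paste0("no drug mention with role ", role),
    n_removed = n_in - length(kept_ids), n_out = length(kept_ids)
  ))
  sr
}

#' Full preprocessing chain
#'
#' [as_safety_reports()] then [deduplicate()], [normalize_report_drugs()],
#' [quality_filter()] and [restrict_role()], in the canonical order.
#'
#' @inheritParams as_safety_reports
#' @inheritParams quality_filter
#' @inheritParams restrict_role
#' @param bundle a [vocabulary_bundle()].
#' @return a preprocessed `safety_reports` object.
#' @export
preprocess_reports <- function(raw, bundle, role = "PS",
                               window_start = "2012-10-01",
                               window_end = NULL) {
  as_safety_reports(raw) |>
    deduplicate() |>
    normalize_report_drugs(bundle) |>
    quality_filter(window_start = window_start, window_end = window_end) |>
    restrict_role(role)
}

#' Attrition log of a report collection
#'
#' @param sr a `safety_reports` object.
#' @return tibble with columns `stage`, `rule`, `n_removed`, `n_out`.
#' @export
attrition_log <- function(sr) sr$attrition

#' Number of reports in a collection
#' @param sr a `safety_reports` object.
#' @return integer count of cases.
#' @export
n_reports <- function(sr) nrow(sr$cases)

#' @export
print.safety_reports <- function(x, ...) {
  cat("<safety_reports>", nrow(x$cases),
      if (x$dedup_done) "cases" else "submissions")
  if (!is.na(x$role)) cat(", role", x$role)
  cat("\n  drug mentions:", nrow(x$drugs),
      " reactions:", nrow(x$reactions),
      " outcome rows:", nrow(x$outcomes), "\n")
  invisible(x)
}
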