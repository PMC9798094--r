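# Disproportionality analysis. Both statistics share one shrunk
# observed/expected ratio:
#
#   n_expected = n_drug * n_event / n_total
#   ROR  = (a + 0.5) / (n_expected + 0.5)
#   IC   = log2(ROR)                                  [bits]
#   ROR025 = exp(ln ROR - z * sqrt(1/a + 1/b + 1/c + 1/d)),  z = 1.96
#   IC025  = IC - 3.3 * (a + 0.5)^(-1/2) - 2 * (a + 0.5)^(-3/2)
#
# The +0.5 shrinkage pulls rare-event ratios toward 1 for conservatism;
# the IC025 penalty is the standard credibility-interval shrinkage
# approximation and vanishes as a grows. A signal is significant when
# ROR025 > 1 with at least `min_cases` reports, or IC025 > 0; strong
# when additionally IC025 > 4.

#' Build 2x2 contingency tables
#'
#' Vectorized constructor from the four cell counts of the report-level
#' 2x2 table: `a` reports with target drug and target event, `b` target
#' drug and other events, `c` other drugs and target event, `d` the
#' rest. Margins and the expected count are derived.
#'
#' @param a,b,c,d non-negative counts (recycled to common length).
#' @return tibble with the cells, margins and `n_expected`.
#' @export
#' @examples
#' contingency_table(15, 35, 60, 890)   # n_expected = 50*75/1000 = 3.75
contingency_table <- function(a, b, c, d) {
  tab <- tibble::tibble(a = as.numeric(a), b = as.numeric(b),
                        c = as.numeric(c), d = as.numeric(d))
  if (any(tab < 0, na.rm = TRUE)) stop_pv("contingency cells must be >= 0")
  tab$n_drug <- tab$a + tab$b
  tab$n_event <- tab$a + tab$c
  tab$n_total <- tab$a + tab$b + tab$c + tab$d
  if (any(tab$n_total == 0)) stop_pv("contingency table with n_total = 0")
  tab$n_expected <- tab$n_drug * tab$n_event / tab$n_total
  tab
}

#' Shrunk reporting odds ratio
#'
#' `(a + 0.5) / (n_expected + 0.5)`: strictly positive, equal to 1 when
#' the observed count matches expectation, and pulled toward 1 for small
#' counts by the additive 0.5.
#'
#' @param table a contingency tibble from [contingency_table()].
#' @return numeric vector of shrunk RORs.
#' @export
shrunk_ror <- function(table) {
  (table$a + 0.5) / (table$n_expected + 0.5)
}

#' Lower 95% bound of the reporting odds ratio
#'
#' `exp(ln ROR - z * sqrt(1/a + 1/b + 1/c + 1/d))`. The variance term is
#' the classical 2x2 log-odds standard error, so the bound is undefined
#' (`NA`) whenever any cell is zero; the 0.5 shrinkage applies to the
#' ratio, not to the variance cells. By default the interval is centred
#' on the shrunk ROR; `center = "crude"` centres it on the classical
#' cross-product ratio `ad/bc` instead.
#'
#' @param table a contingency tibble.
#' @param z normal quantile (default 1.96 for a 95% bound).
#' @param center `"shrunk"` (default) or `"crude"`.
#' @return numeric vector; `NA` where a zero cell makes the bound
#'   undefined.
#' @export
ror_lower_bound <- function(table, z = 1.96, center = c("shrunk", "crude")) {
  center <- match.arg(center)
  point <- switch(center,
    shrunk = shrunk_ror(table),
    crude = (table$a * table$d) / (table$b * table$c)
  )
  se <- sqrt(1 / table$a + 1 / table$b + 1 / table$c + 1 / table$d)
  out <- exp(log(point) - z * se)
  out[table$a == 0 | table$b == 0 | table$c == 0 | table$d == 0] <- NA_real_
  out
}

#' Information component and its lower 95% bound
#'
#' `IC = log2((a + 0.5) / (n_expected + 0.5))` in bits — identical to
#' `log2(shrunk ROR)` by construction — and
#' `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`, a credibility-
#' interval shrinkage penalty that is strictly positive and decays to
#' zero as the observed count grows.
#'
#' @param table a contingency tibble.
#' @return tibble with columns `ic` and `ic025`.
#' @export
information_component <- function(table) {
  ic <- log2(shrunk_ror(table))
  a5 <- table$a + 0.5
  ic025 <- ic - 3.3 * a5^(-0.5) - 2 * a5^(-1.5)
  tibble::tibble(ic = ic, ic025 = ic025)
}

#' Classify signals from the decision thresholds
#'
#' `significant` when `ror025 > 1` with at least `min_cases` reports, or
#' `ic025 > 0` (both strict inequalities); `strong` when significant and
#' `ic025 > strong_cutoff`. A missing `ror025` (zero cell) leaves only
#' the IC path open.
#'
#' @param ror025 numeric vector (may contain `NA`).
#' @param a observed report counts.
#' @param ic025 numeric vector.
#' @param min_cases minimum report count for the ROR path (default 3).
#' @param strong_cutoff IC025 cutoff for a strong signal (default 4).
#' @return tibble with logical columns `significant` and `strong`.
#' @export
classify_signal <- function(ror025, a, ic025, min_cases = 3,
                            strong_cutoff = 4) {
  ror_path <- !is.na(ror025) & ror025 > 1 & a >= min_cases
  ic_path <- !is.na(ic025) & ic025 > 0
  significant <- ror_path | ic_path
  tibble::tibble(
    significant = significant,
    strong = significant & !is.na(ic025) & ic025 > strong_cutoff
  )
}

# Full statistics block for a table of contingency rows.
dpa_statistics <- function(table, min_cases = 3, strong_cutoff = 4,
                           z = 1.96, ror_center = "shrunk") {
  ror <- shrunk_ror(table)
  ror025 <- ror_lower_bound(table, z = z, center = ror_center)
  ic <- information_component(table)
  flags <- classify_signal(ror025, table$a, ic$ic025,
                           min_cases = min_cases,
                           strong_cutoff = strong_cutoff)
  dplyr::bind_cols(table, tibble::tibble(ror = ror, ror025 = ror025),
                   ic, flags)
}

# ---- report-level counting -------------------------------------------------

# Distinct (caseid, event) pairs at the requested level. A report counts
# once per PT however often the PT is listed, and once per SOC however
# many of its PTs map there. ime_only restricts to IME-designated PTs
# *before* SOC mapping.
report_events <- function(sr, level, bundle, ime_only = FALSE) {
  re <- sr$reactions
  key <- norm_key(re$pt)
  if (ime_only) {
    keep <- key %in% bundle$ime_set
    re <- re[keep, , drop = FALSE]
    key <- key[keep]
  }
  if (level == "pt") {
    display <- unname(bundle$pt_display[key])
    display[is.na(display)] <- re$pt[is.na(display)]
    out <- tibble::tibble(caseid = re$caseid, event = display)
  } else if (level == "soc") {
    soc <- unname(bundle$pt_to_soc[key])
    soc[is.na(soc)] <- "UNMAPPED"
    out <- tibble::tibble(caseid = re$caseid, event = soc)
  } else {
    stop_pv("level must be 'pt' or 'soc'")
  }
  dplyr::distinct(out)
}

# Universe of analyzable reports: cases carrying at least one reaction.
analysis_universe <- function(sr) {
  intersect(sr$cases$caseid, unique(sr$reactions$caseid))
}

# Count contingency tables for one target drug over a set of events
# within a given universe of caseids.
count_drug_events <- function(suspects, rep_evt, universe, drug, events) {
  sus <- suspects[suspects$drug == drug & suspects$caseid %in% universe, ]
  evt <- rep_evt[rep_evt$caseid %in% universe, ]
  n_total <- length(universe)
  n_drug <- dplyr::n_distinct(sus$caseid)
  n_event <- evt |> dplyr::count(.data$event, name = "n_event")
  a_tab <- evt |>
    dplyr::semi_join(sus, by = "caseid") |>
    dplyr::count(.data$event, name = "a")
  out <- tibble::tibble(event = events) |>
    dplyr::left_join(n_event, by = "event") |>
    dplyr::left_join(a_tab, by = "event") |>
    dplyr::mutate(
      n_event = dplyr::coalesce(.data$n_event, 0L),
      a = as.numeric(dplyr::coalesce(.data$a, 0L)),
      b = n_drug - .data$a,
      c = .data$n_event - .data$a,
      d = n_total - n_drug - .data$c
    )
  contingency_table(out$a, out$b, out$c, out$d) |>
    dplyr::mutate(event = out$event, .before = 1)
}

#' Batch disproportionality scan
#'
#' Computes, for each target drug and each event at the requested level,
#' the report-level 2x2 table, the shrunk ROR and IC with 95% lower
#' bounds, and the signal flags. Two background contexts are available:
#' `"all-other-drugs"` keeps the whole universe and splits it at the
#' target drug; `"comparator-class"` first restricts the universe to
#' reports whose suspect drug is the target or a member of the
#' comparator class (so the other target drugs drop out of the
#' background entirely), then splits.
#'
#' @param sr a preprocessed `safety_reports` object (after
#'   [restrict_role()]).
#' @param bundle a [vocabulary_bundle()].
#' @param drugs character vector of canonical target drug ids.
#' @param level `"pt"` or `"soc"`.
#' @param context `"all-other-drugs"` or `"comparator-class"`.
#' @param ime_only restrict events to IME-designated PTs (before SOC
#'   mapping at SOC level).
#' @param events optional character vector of events to score; default
#'   all events observed in the universe at the requested level.
#' @param min_cases minimum case count for the ROR significance path.
#' @param strong_cutoff IC025 cutoff for strong signals.
#' @param z normal quantile for the ROR bound.
#' @param ror_center `"shrunk"` or `"crude"` centring of the ROR bound.
#' @param comparators canonical ids of the comparator class; default the
#'   bundle's `"non-TAD-antifungal"` drugs.
#' @return a tibble of class `signal_table`: one row per (drug, event).
#' @export
signal_scan <- function(sr, bundle, drugs,
                        level = c("pt", "soc"),
                        context = c("all-other-drugs", "comparator-class"),
                        ime_only = FALSE, events = NULL,
                        min_cases = 3, strong_cutoff = 4, z = 1.96,
                        ror_center = "shrunk", comparators = NULL) {
  level <- match.arg(level)
  context <- match.arg(context)
  if (!length(drugs)) stop_pv("no target drugs given")
  if (is.null(sr$suspects)) {
    stop_pv("reports are not role-restricted; run restrict_role() first")
  }
  if (is.null(comparators)) comparators <- drugs_in_class(bundle, "non-TAD-antifungal")

  rep_evt <- report_events(sr, level, bundle, ime_only = ime_only)
  uni_all <- analysis_universe(sr)
  if (is.null(events)) events <- sort(unique(rep_evt$event))

  rows <- lapply(drugs, function(drug) {
    universe <- if (context == "all-other-drugs") {
      uni_all
    } else {
      in_class <- sr$suspects$drug %in% c(drug, comparators)
      intersect(uni_all, unique(sr$suspects$caseid[in_class]))
    }
    if (!length(universe)) {
      return(NULL)
    }
    tab <- count_drug_events(sr$suspects, rep_evt, universe, drug, events)
    tab$drug <- drug
    tab$absent <- tab$n_drug == 0
    tab
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(structure(tibble::tibble(), class = c("signal_table", "tbl_df",
                                                 "tbl", "data.frame")))
  }
  out <- dpa_statistics(out, min_cases = min_cases,
                        strong_cutoff = strong_cutoff, z = z,
                        ror_center = ror_center)
  out$level <- level
  out$context <- context
  if (level == "pt") {
    cls <- classify_event(out$event, bundle)
    out$soc <- cls$soc
    out$ime <- cls$ime
  } else {
    out$soc <- out$event
    out$ime <- NA
  }
  out <- dplyr::select(out, dplyr::all_of(c(
    "drug", "level", "event", "soc", "ime", "context",
    "a", "b", "c", "d", "n_drug", "n_event", "n_total", "n_expected",
    "ror", "ror025", "ic", "ic025", "significant", "strong", "absent")))
  class(out) <- c("signal_table", class(tibble::tibble()))
  out
}

#' Contingency table for a single drug-event pair
#'
#' Convenience wrapper around the batch counting path for one pair.
#'
#' @inheritParams signal_scan
#' @param drug one canonical drug id.
#' @param event one event (PT or SOC label, per `level`).
#' @return one-row tibble with the 2x2 cells, margins and `n_expected`;
#'   the `absent` column flags a drug unseen in the universe
#'   (`a = b = 0`).
#' @export
build_contingency <- function(sr, bundle, drug, event,
                              level = c("pt", "soc"),
                              context = c("all-other-drugs", "comparator-class"),
                              comparators = NULL) {
  level <- match.arg(level)
  context <- match.arg(context)
  res <- signal_scan(sr, bundle, drugs = drug, level = level,
                     context = context, events = event,
                     comparators = comparators)
  dplyr::select(res, dplyr::all_of(c(
    "drug", "event", "a", "b", "c", "d",
    "n_drug", "n_event", "n_total", "n_expected", "absent")))
}
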