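# Signal spectra: SOC-level dual AE/IME table and PT-level IME spectra
# per drug, with deterministic ordering and a heatmap rendering.

#' SOC-level disproportionality of a drug group
#'
#' Treats `drugs` as one target group and scores every SOC against the
#' chosen background twice over the same universe: once for all events
#' and once for the IME-designated subset of PTs. SOC rows whose event
#' count falls below `min_cases` in a pass have that pass's statistics
#' suppressed (`NA`), mirroring the convention of printing `---` for
#' unstable cells.
#'
#' @inheritParams signal_scan
#' @param drugs canonical ids forming the target group.
#' @return tibble of class `spectrum_table` with one row per SOC and
#'   paired columns `n_ae, ic025_ae, ror025_ae, sig_ae` /
#'   `n_ime, ic025_ime, ror025_ime, sig_ime`.
#' @export
soc_analysis <- function(sr, bundle, drugs,
                         context = c("all-other-drugs", "comparator-class"),
                         min_cases = 3, comparators = NULL) {
  context <- match.arg(context)
  grouped <- group_suspects(sr, drugs)
  pass <- function(ime_only, suffix) {
    res <- signal_scan(grouped, bundle, drugs = ".target_group",
                       level = "soc", context = context,
                       ime_only = ime_only, min_cases = min_cases,
                       comparators = comparators)
    res |>
      dplyr::transmute(
        soc = .data$event,
        "n_{suffix}" := .data$a,
        "ic025_{suffix}" := ifelse(.data$a >= min_cases, .data$ic025, NA_real_),
        "ror025_{suffix}" := ifelse(.data$a >= min_cases, .data$ror025, NA_real_),
        "sig_{suffix}" := ifelse(.data$a >= min_cases, .data$significant, NA)
      )
  }
  ae <- pass(FALSE, "ae")
  ime <- pass(TRUE, "ime")
  out <- dplyr::full_join(ae, ime, by = "soc") |>
    dplyr::mutate(dplyr::across(dplyr::starts_with("n_"),
                                ~ dplyr::coalesce(.x, 0))) |>
    dplyr::arrange(.data$soc)
  attr(out, "context") <- context
  class(out) <- c("spectrum_table", class(tibble::tibble()))
  out
}

# Relabel the suspect drugs in `drugs` as one pseudo-drug so the batch
# scanner scores the group as a unit. Other suspects keep their ids.
group_suspects <- function(sr, drugs) {
  sr$suspects <- sr$suspects |>
    dplyr::mutate(drug = ifelse(.data$drug %in% drugs,
                                ".target_group", .data$drug)) |>
    dplyr::distinct()
  sr
}

#' PT-level IME signal spectrum
#'
#' Scores every IME-designated PT for each target drug separately,
#' keeping only PTs with at least `min_cases` reports for that drug
#' (rarer PTs are prone to false-positive signals). Rows are ordered by
#' SOC and then PT alphabetically, so the layout is deterministic.
#'
#' @inheritParams signal_scan
#' @return a `signal_table` restricted to IME PTs with `a >= min_cases`,
#'   ordered by (drug, SOC, PT).
#' @export
ime_spectrum <- function(sr, bundle, drugs,
                         context = c("all-other-drugs", "comparator-class"),
                         min_cases = 3, strong_cutoff = 4,
                         comparators = NULL) {
  context <- match.arg(context)
  res <- signal_scan(sr, bundle, drugs = drugs, level = "pt",
                     context = context, ime_only = TRUE,
                     min_cases = min_cases, strong_cutoff = strong_cutoff,
                     comparators = comparators)
  if (!nrow(res)) return(res)
  out <- res |>
    dplyr::filter(.data$a >= min_cases) |>
    dplyr::arrange(.data$drug, .data$soc, .data$event)
  attr(out, "signal_counts") <-
    out |>
    dplyr::filter(.data$significant) |>
    dplyr::count(.data$drug, name = "n_signals")
  out
}

#' Render a signal spectrum as a heatmap
#'
#' Selects the `top_n` significant rows (ordered by IC025 descending,
#' ties broken alphabetically by event) and draws a drugs-by-events tile
#' panel annotated with IC025, marking strong signals. The tidy table —
#' every input row plus its display rank (`NA` outside the rendered
#' subset) — is always produced, and written even when the figure is
#' skipped for an empty table.
#'
#' @param table a `signal_table` (e.g. from [ime_spectrum()]).
#' @param top_n number of significant rows to render; `Inf` for all.
#' @param file optional path for the figure (PNG/SVG via [ggplot2::ggsave()]).
#' @param table_file optional path for the tidy table CSV.
#' @return list with `figure` (a ggplot or `NULL`) and `table` (tibble
#'   with `display_rank`).
#' @export
render_spectrum <- function(table, top_n = 30, file = NULL,
                            table_file = NULL) {
  tidy <- tibble::as_tibble(table)
  if (nrow(tidy)) {
    sig <- tidy |>
      dplyr::filter(.data$significant) |>
      dplyr::arrange(dplyr::desc(.data$ic025), .data$event, .data$drug)
    ranked <- utils::head(sig, top_n) |>
      dplyr::mutate(display_rank = dplyr::row_number()) |>
      dplyr::select(dplyr::all_of(c("drug", "event", "display_rank")))
    tidy <- dplyr::left_join(tidy, ranked, by = c("drug", "event"))
  } else {
    tidy$display_rank <- integer(0)
  }
  if (!is.null(table_file)) {
    readr::write_csv(tidy, table_file, progress = FALSE)
  }
  fig <- NULL
  shown <- dplyr::filter(tidy, !is.na(.data$display_rank))
  if (nrow(shown)) {
    evt_order <- shown |>
      dplyr::distinct(.data$soc, .data$event) |>
      dplyr::arrange(.data$soc, .data$event)
    shown$event_f <- factor(shown$event, levels = rev(evt_order$event))
    fig <- ggplot2::ggplot(shown, ggplot2::aes(
      x = .data$drug, y = .data$event_f, fill = .data$ic025)) +
      ggplot2::geom_tile(color = "grey80") +
      ggplot2::geom_text(ggplot2::aes(
        label = paste0(sprintf("%.2f", .data$ic025),
                       ifelse(.data$strong, " *", ""))), size = 2.8) +
      ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                    high = "firebrick", midpoint = 0,
                                    name = "IC025") +
      ggplot2::labs(x = NULL, y = NULL,
                    caption = "* strong signal (IC025 > 4)") +
      ggplot2::theme_minimal(base_size = 9)
    if (!is.null(file)) {
      ggplot2::ggsave(file, fig, width = 7,
                      height = max(2, 0.25 * nrow(evt_order) + 1.5),
                      dpi = 150)
    }
  } else if (!is.null(file)) {
    rlang::warn("empty spectrum: no figure written")
  }
  list(figure = fig, table = tidy)
}
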