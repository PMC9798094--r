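# End-to-end orchestration: ingest (or synthesize) -> preprocess ->
# vocabulary -> disproportionality -> spectra, cohort tables and
# figures, written to an artifact directory.

#' Run the full signal-detection pipeline
#'
#' Executes the canonical analysis on either FAERS-style quarter files
#' or a synthetic scenario: preprocessing with attrition logging,
#' SOC-level dual AE/IME analysis and PT-level IME spectra under both
#' background contexts, cohort summaries, drug-wise shares, the
#' comedication-incidence grid, and the outcome cross-tab for the
#' common significant signals. All tidy tables are written as CSV;
#' figures as PNG.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `quarters` (list of per-table path lists for [read_faers_quarter()])
#'   *or* `scenario` (a [synthetic_scenario()]); `seed` (for synthetic
#'   input); `drugs` (target canonical ids; default the bundle's TAD
#'   class); `comparators` (default the bundle's non-TAD antifungals);
#'   `window_start`, `window_end`; `min_cases` (3), `strong_cutoff` (4);
#'   `top_n` (30); `out_dir`.
#' @param bundle a [vocabulary_bundle()] (default the shipped mock
#'   vocabulary).
#' @return list of artifact paths and in-memory results, invisibly.
#' @export
run_pipeline <- function(config, bundle = load_vocabulary()) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_pv("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    quarters = NULL, scenario = NULL, seed = 1L,
    drugs = NULL, comparators = NULL,
    window_start = "2012-10-01", window_end = NULL,
    min_cases = 3, strong_cutoff = 4, top_n = 30,
    out_dir = "pvsignal_artifacts"
  ), config)
  if (is.null(cfg$drugs)) cfg$drugs <- drugs_in_class(bundle, "TAD")
  if (!length(cfg$drugs)) stop_pv("config has an empty target drug list")
  if (is.null(cfg$quarters) && is.null(cfg$scenario)) {
    stop_pv("config needs either `quarters` (paths) or `scenario` (synthetic)")
  }
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  p <- function(...) file.path(cfg$out_dir, ...)

  if (!is.null(cfg$scenario)) {
    gen <- generate_faers(cfg$scenario, seed = cfg$seed)
    raw <- gen$tables
  } else {
    raws <- lapply(cfg$quarters, read_faers_quarter)
    raw <- bind_quarters(raws)
  }
  sr <- preprocess_reports(raw, bundle,
                           window_start = cfg$window_start,
                           window_end = cfg$window_end)
  readr::write_csv(attrition_log(sr), p("attrition.csv"), progress = FALSE)

  results <- list(attrition = attrition_log(sr))
  for (ctx in c("all-other-drugs", "comparator-class")) {
    tag <- if (ctx == "all-other-drugs") "all" else "class"
    soc <- soc_analysis(sr, bundle, cfg$drugs, context = ctx,
                        min_cases = cfg$min_cases,
                        comparators = cfg$comparators)
    readr::write_csv(soc, p(paste0("soc_", tag, ".csv")), progress = FALSE)
    spec <- ime_spectrum(sr, bundle, cfg$drugs, context = ctx,
                         min_cases = cfg$min_cases,
                         strong_cutoff = cfg$strong_cutoff,
                         comparators = cfg$comparators)
    write_signal_table(spec, p(paste0("ime_spectrum_", tag, ".csv")))
    render_spectrum(spec, top_n = cfg$top_n,
                    file = if (nrow(spec)) p(paste0("spectrum_", tag, ".png")),
                    table_file = p(paste0("spectrum_", tag, "_tidy.csv")))
    results[[paste0("soc_", tag)]] <- soc
    results[[paste0("spectrum_", tag)]] <- spec
  }

  for (coh in c("AE", "IME")) {
    cs <- summarize_cohort(sr, bundle, cohort = coh)
    readr::write_csv(
      dplyr::bind_rows(
        dplyr::mutate(cs$sex, partition = "sex"),
        dplyr::mutate(cs$age_bands, partition = "age"),
        dplyr::mutate(cs$years, partition = "year",
                      stratum = as.character(.data$stratum)),
        dplyr::mutate(cs$countries, partition = "country"),
        dplyr::mutate(cs$outcomes, partition = "outcome",
                      stratum = .data$label) |>
          dplyr::select(-dplyr::all_of(c("code", "label")))
      ),
      p(paste0("cohort_", tolower(coh), ".csv")), progress = FALSE)
    results[[paste0("cohort_", tolower(coh))]] <- cs
  }

  shares <- drugwise_share(sr, bundle, cfg$drugs)
  readr::write_csv(shares, p("drug_shares.csv"), progress = FALSE)
  grid <- comedication_incidence(sr, bundle, cfg$drugs)
  readr::write_csv(grid, p("comedication_incidence.csv"), progress = FALSE)
  render_comedication(grid, file = p("comedication_incidence.png"))
  xtab <- significant_ime_outcomes(sr, bundle)
  readr::write_csv(xtab, p("signal_outcome_crosstab.csv"), progress = FALSE)
  results$shares <- shares
  results$comedication <- grid
  results$crosstab <- xtab
  results$reports <- sr
  results$out_dir <- cfg$out_dir
  invisible(results)
}

# Concatenate several quarters' tables into one faers_tables object.
bind_quarters <- function(raws) {
  out <- raws[[1]]
  if (length(raws) > 1) {
    for (tab in c("demo", "drug", "reac", "outc", "ther", "indi")) {
      out[[tab]] <- dplyr::bind_rows(lapply(raws, `[[`, tab))
    }
    out$manifest <- dplyr::bind_rows(lapply(raws, `[[`, "manifest"))
  }
  out
}

#' One-command synthetic demonstration
#'
#' Generates the default synthetic scenario with a handful of planted
#' drug--event associations and runs the full pipeline on it.
#'
#' @param seed integer seed.
#' @param out_dir artifact directory.
#' @param n_reports scenario size.
#' @return the [run_pipeline()] result, invisibly.
#' @export
demo_run <- function(seed = 7, out_dir = tempfile("pvsignal_demo_"),
                     n_reports = 20000) {
  bundle <- load_vocabulary()
  planted <- tibble::tibble(
    drug = c("voriconazole", "voriconazole", "fluconazole", "posaconazole"),
    pt = c("Cholestasis", "Hallucination", "QT interval prolonged",
           "Drug-induced liver injury"),
    lambda = c(6, 4, 5, 4)
  )
  scenario <- default_scenario(n_reports = n_reports, bundle = bundle,
                               planted = planted, seed = seed)
  run_pipeline(list(scenario = scenario, seed = seed, out_dir = out_dir),
               bundle = bundle)
}
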