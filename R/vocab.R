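# Vocabulary normalization: drug synonyms, PT -> SOC mapping, IME
# designation, outcome-code severity. The package ships a mock vocabulary
# (inst/extdata) spanning 27 SOCs because MedDRA and the EMA important
# medical event list are licensed and cannot be redistributed; users with
# licensed copies supply their own CSVs in the same layout.

#' Default clinical outcome code labels
#'
#' The seven FAERS outcome codes and their labels.
#' @return named character vector, code -> label.
#' @export
outcome_code_map <- function() {
  c(DE = "Death", LT = "Life-Threatening", HO = "Hospitalization",
    DS = "Disability", CA = "Congenital Anomaly",
    RI = "Required Intervention", OT = "Other Serious")
}

#' Assemble a vocabulary bundle
#'
#' Bundles the four lookup tables the pipeline needs: a drug synonym
#' dictionary (raw reported name -> canonical drug id with a class tag),
#' a PT -> primary SOC map, the set of PTs designated important medical
#' events (IME), and the outcome-code label map. Lookups are
#' case-, whitespace- and punctuation-insensitive.
#'
#' @param synonyms data frame with columns `raw_name`, `canonical`,
#'   `class` (e.g. `"TAD"`, `"non-TAD-antifungal"`).
#' @param pt_soc data frame with columns `pt`, `soc`; each PT maps to
#'   exactly one primary SOC.
#' @param ime data frame with column `pt` (must be a subset of `pt_soc$pt`)
#'   or a character vector of PTs.
#' @param outcome_map named character vector, outcome code -> label.
#' @param meta optional list of metadata (e.g. vocabulary version).
#' @return an object of class `vocabulary_bundle`.
#' @export
vocabulary_bundle <- function(synonyms, pt_soc, ime,
                              outcome_map = outcome_code_map(),
                              meta = list()) {
  synonyms <- tibble::as_tibble(synonyms)
  pt_soc <- tibble::as_tibble(pt_soc)
  if (is.character(ime)) ime <- tibble::tibble(pt = ime)
  ime <- tibble::as_tibble(ime)
  stopifnot(all(c("raw_name", "canonical", "class") %in% names(synonyms)),
            all(c("pt", "soc") %in% names(pt_soc)),
            "pt" %in% names(ime))

  syn_key <- norm_key(synonyms$raw_name)
  if (anyDuplicated(syn_key)) {
    dup <- synonyms$raw_name[duplicated(syn_key)]
    stop_pv("duplicate synonym keys in dictionary: ",
            paste(unique(dup), collapse = ", "))
  }
  pt_key <- norm_key(pt_soc$pt)
  if (anyDuplicated(pt_key)) {
    stop_pv("a PT maps to more than one primary SOC: ",
            paste(unique(pt_soc$pt[duplicated(pt_key)]), collapse = ", "))
  }
  ime_key <- unique(norm_key(ime$pt))
  missing_ime <- setdiff(ime_key, pt_key)
  if (length(missing_ime)) {
    stop_pv("IME list contains PTs absent from the PT->SOC map: ",
            paste(head(missing_ime, 5), collapse = ", "))
  }

  drug_class <- synonyms |>
    dplyr::distinct(.data$canonical, .data$class) |>
    dplyr::group_by(.data$canonical) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  structure(list(
    synonyms = synonyms,
    syn_map = setNames(synonyms$canonical, syn_key),
    drug_class = setNames(drug_class$class, drug_class$canonical),
    pt_soc = pt_soc,
    pt_to_soc = setNames(pt_soc$soc, pt_key),
    pt_display = setNames(pt_soc$pt, pt_key),
    ime_set = ime_key,
    outcome_map = outcome_map,
    meta = meta
  ), class = "vocabulary_bundle")
}

#' Load a vocabulary bundle from CSV files
#'
#' Reads `synonyms.csv` (`raw_name,canonical,class`), `pt_soc.csv`
#' (`pt,soc`) and `ime.csv` (`pt`) from a directory. With `dir = NULL`
#' the mock vocabulary shipped with the package is loaded: 200+ PTs
#' spanning 27 SOCs with an IME subset, and synonym dictionaries for the
#' five triazole antifungals (TADs) plus a non-TAD antifungal comparator
#' class (amphotericin B, echinocandins, flucytosine, terbinafine).
#'
#' @param dir directory containing the three CSVs, or `NULL` for the
#'   shipped mock vocabulary.
#' @return a [vocabulary_bundle()].
#' @export
load_vocabulary <- function(dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "pvsignal")
  read_csv_q <- function(f) {
    readr::read_csv(file.path(dir, f), col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
  }
  vocabulary_bundle(
    synonyms = read_csv_q("synonyms.csv"),
    pt_soc = read_csv_q("pt_soc.csv"),
    ime = read_csv_q("ime.csv"),
    meta = list(source = "pvsignal mock vocabulary", version = NA_character_)
  )
}

#' @export
print.vocabulary_bundle <- function(x, ...) {
  cat("<vocabulary_bundle>\n")
  cat("  synonyms:", nrow(x$synonyms), "->",
      length(unique(x$synonyms$canonical)), "canonical drugs\n")
  cat("  PTs:", nrow(x$pt_soc), "across",
      length(unique(x$pt_soc$soc)), "SOCs;",
      length(x$ime_set), "flagged IME\n")
  invisible(x)
}

#' Normalize a reported drug name
#'
#' Case-, whitespace- and punctuation-insensitive lookup of raw reported
#' drug names (trade, generic or chemical) against the synonym
#' dictionary. Unmatched names return `NA`.
#'
#' @param raw_name character vector of reported names.
#' @param bundle a [vocabulary_bundle()].
#' @return character vector of canonical drug ids (`NA` where unmatched).
#' @export
#' @examples
#' b <- load_vocabulary()
#' normalize_drug(c("VFEND", "fluconazole  ", "aspirin"), b)
normalize_drug <- function(raw_name, bundle) {
  out <- unname(bundle$syn_map[norm_key(raw_name)])
  out[is.na(raw_name) | trimws(raw_name) == ""] <- NA_character_
  out
}

#' Classify a reaction PT
#'
#' Maps each PT to its primary SOC and IME designation. PTs absent from
#' the vocabulary are routed to the explicit `"UNMAPPED"` SOC with
#' `ime = FALSE`; the function never errors on unknown terms.
#'
#' @param pt character vector of preferred terms.
#' @param bundle a [vocabulary_bundle()].
#' @return tibble with columns `pt`, `soc`, `ime`.
#' @export
classify_event <- function(pt, bundle) {
  key <- norm_key(pt)
  soc <- unname(bundle$pt_to_soc[key])
  soc[is.na(soc) | key == ""] <- "UNMAPPED"
  tibble::tibble(
    pt = pt,
    soc = soc,
    ime = key %in% bundle$ime_set
  )
}

#' Serious-outcome classification of an outcome code set
#'
#' Two named definitions of "serious" coexist and are never silently
#' interchanged: `"strict4"` counts Death, Life-Threatening, Disability
#' and Hospitalization; `"nonhosp5"` counts Death, Life-Threatening,
#' Disability, Congenital Anomaly and Required Intervention (the
#' five-category sum used in headline serious-outcome tallies).
#'
#' @param outcomes character vector of outcome codes for one report.
#' @param definition `"strict4"` or `"nonhosp5"`.
#' @param bundle optional [vocabulary_bundle()] supplying labels.
#' @return list with `serious` (logical) and `labels` (character).
#' @export
#' @examples
#' outcome_severity(c("HO", "OT"))        # serious under strict4
#' outcome_severity("OT")$serious         # FALSE
outcome_severity <- function(outcomes, definition = "strict4",
                             bundle = NULL) {
  map <- if (is.null(bundle)) outcome_code_map() else bundle$outcome_map
  codes <- unique(toupper(trimws(outcomes)))
  unknown <- setdiff(codes, names(map))
  if (length(unknown)) {
    rlang::warn(paste("ignoring unknown outcome codes:",
                      paste(unknown, collapse = ", ")))
    codes <- intersect(codes, names(map))
  }
  list(
    serious = length(intersect(codes, serious_definition(definition))) > 0,
    labels = unname(map[codes])
  )
}

# The category sets behind the two named serious-outcome definitions.
serious_definition <- function(definition) {
  switch(definition,
    strict4 = c("DE", "LT", "DS", "HO"),
    nonhosp5 = c("DE", "LT", "DS", "CA", "RI"),
    stop_pv("unknown serious-outcome definition: ", definition)
  )
}

#' Drugs belonging to a vocabulary class
#'
#' @param bundle a [vocabulary_bundle()].
#' @param class class tag, e.g. `"TAD"` or `"non-TAD-antifungal"`.
#' @return character vector of canonical drug ids.
#' @export
drugs_in_class <- function(bundle, class) {
  names(bundle$drug_class)[bundle$drug_class == class]
}
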