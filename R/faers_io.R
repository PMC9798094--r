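# Reading and writing FAERS-dialect quarterly ASCII tables. The dialect
# is one header line and "$"-delimited fields with no quoting; an
# embedded "$" does not occur in the dialect, which read_faers_quarter
# asserts by rejecting rows with a surplus field count.

faers_mandatory <- list(
  demo = c("primaryid", "caseid", "fda_dt"),
  drug = c("primaryid", "role_cod", "drugname"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  ther = "primaryid",
  indi = "primaryid"
)

#' Read one FAERS-style quarter
#'
#' Parses the six `$`-delimited ASCII tables of a FAERS quarterly release
#' (DEMO, DRUG, REAC, OUTC, THER, INDI). Tables not supplied are returned
#' empty. Rows with the wrong field count are rejected and counted in the
#' manifest, never silently dropped; a missing mandatory column is a hard
#' error naming the table and column; an unparseable date leaves the
#' field missing but keeps the row.
#'
#' Dates are retained at their reported precision (`YYYYMMDD`, `YYYYMM`
#' or `YYYY`) as ISO strings with a precision flag. Ages are harmonized
#' to years from the FAERS unit code before any filtering.
#'
#' @param paths named list/vector of file paths; names among
#'   `demo, drug, reac, outc, ther, indi`.
#' @param delim field delimiter (default `"$"`).
#' @param quarter_label optional label stored in the manifest.
#' @return an object of class `faers_tables`: the six tibbles plus a
#'   `manifest` tibble of per-table read/accept/reject counts.
#' @export
read_faers_quarter <- function(paths, delim = "$", quarter_label = NA_character_) {
  paths <- as.list(paths)
  unknown <- setdiff(names(paths), names(faers_mandatory))
  if (length(unknown)) stop_pv("unknown table name(s): ", paste(unknown, collapse = ", "))
  tables <- list()
  manifest <- list()
  for (tab in names(faers_mandatory)) {
    path <- paths[[tab]]
    if (is.null(path)) {
      tables[[tab]] <- empty_faers_table(tab)
      next
    }
    if (!file.exists(path)) stop_pv("file not found for table ", tab, ": ", path)
    parsed <- read_dollar_table(path, delim)
    missing_cols <- setdiff(faers_mandatory[[tab]], names(parsed$data))
    if (length(missing_cols)) {
      stop_pv("table ", toupper(tab), " is missing mandatory column(s): ",
              paste(missing_cols, collapse = ", "))
    }
    tables[[tab]] <- postprocess_faers_table(tab, parsed$data)
    manifest[[tab]] <- tibble::tibble(
      table = tab, path = path,
      rows_read = parsed$rows_read,
      rows_accepted = nrow(parsed$data),
      rows_rejected = parsed$rows_rejected,
      reject_reason = parsed$reject_reason
    )
  }
  structure(list(
    demo = tables$demo, drug = tables$drug, reac = tables$reac,
    outc = tables$outc, ther = tables$ther, indi = tables$indi,
    manifest = dplyr::bind_rows(manifest),
    quarter_label = quarter_label
  ), class = "faers_tables")
}

# Split one $-delimited file by hand: no quoting exists in the dialect,
# so a deviant field count identifies a malformed row exactly.
read_dollar_table <- function(path, delim) {
  lines <- readr::read_lines(path, progress = FALSE)
  if (!length(lines)) stop_pv("empty file (no header): ", path)
  header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  header <- tolower(trimws(header))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  rows_read <- length(body)
  if (!rows_read) {
    data <- tibble::as_tibble(setNames(
      replicate(length(header), character(0), simplify = FALSE), header))
    return(list(data = data, rows_read = 0L, rows_rejected = 0L,
                reject_reason = NA_character_))
  }
  parts <- strsplit(body, delim, fixed = TRUE)
  nf <- lengths(parts)
  # trailing empty field is dropped by strsplit; tolerate count-1
  ok <- nf == length(header) | nf == length(header) - 1L
  bad <- sum(!ok)
  parts <- parts[ok]
  cols <- lapply(seq_along(header), function(i) {
    vapply(parts, function(p) if (i <= length(p)) p[i] else "", character(1))
  })
  data <- tibble::as_tibble(setNames(cols, header))
  data[] <- lapply(data, function(x) {
    x <- trimws(x)
    x[x == ""] <- NA_character_
    x
  })
  list(data = data, rows_read = rows_read, rows_rejected = bad,
       reject_reason = if (bad) "field count mismatch" else NA_character_)
}

empty_faers_table <- function(tab) {
  cols <- switch(tab,
    demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
             "reporter_country", "event_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "start_dt", "end_dt"),
    indi = c("primaryid", "indi_pt")
  )
  out <- tibble::as_tibble(setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols))
  postprocess_faers_table(tab, out)
}

postprocess_faers_table <- function(tab, data) {
  if (tab == "demo") {
    for (col in c("age", "age_cod", "sex", "reporter_country", "event_dt")) {
      if (!col %in% names(data)) data[[col]] <- NA_character_
    }
    fd <- parse_faers_date(data$fda_dt)
    data$fda_dt_iso <- fd$iso
    data$fda_dt_num <- fd$num
    data$fda_dt_precision <- fd$precision
    ed <- parse_faers_date(data$event_dt)
    data$event_dt_iso <- ed$iso
    data$age_years <- harmonize_age(data$age, data$age_cod)
    data$sex <- normalize_sex(data$sex)
  }
  if (tab == "drug") {
    if (!"prod_ai" %in% names(data)) data$prod_ai <- NA_character_
    if (!"drug_seq" %in% names(data)) data$drug_seq <- NA_character_
    data$role_cod <- toupper(trimws(data$role_cod))
    bad_role <- !is.na(data$role_cod) & !data$role_cod %in% c("PS", "SS", "C", "I")
    if (any(bad_role)) {
      rlang::warn(paste0(sum(bad_role),
        " DRUG row(s) with role_cod outside {PS,SS,C,I}; kept as-is"))
    }
  }
  if (tab == "ther") {
    for (col in c("start_dt", "end_dt")) {
      if (!col %in% names(data)) data[[col]] <- NA_character_
    }
  }
  if (tab == "indi" && !"indi_pt" %in% names(data)) data$indi_pt <- NA_character_
  data
}

normalize_sex <- function(x) {
  x <- toupper(trimws(x))
  dplyr::case_when(
    x %in% c("M", "MALE") ~ "M",
    x %in% c("F", "FEMALE") ~ "F",
    TRUE ~ "unknown"
  )
}

#' @export
print.faers_tables <- function(x, ...) {
  cat("<faers_tables>",
      if (!is.na(x$quarter_label)) paste0(" [", x$quarter_label, "]"), "\n")
  for (tab in c("demo", "drug", "reac", "outc", "ther", "indi")) {
    cat(sprintf("  %-5s %d rows\n", toupper(tab), nrow(x[[tab]])))
  }
  invisible(x)
}

#' Write a FAERS-style quarter to disk
#'
#' Writes the six tables of a `faers_tables` object as `$`-delimited
#' ASCII files (one header line, no quoting) that [read_faers_quarter()]
#' reads back. Derived columns (parsed dates, harmonized age) are not
#' written; only the dialect's raw columns are.
#'
#' @param tables a `faers_tables` object.
#' @param dir output directory (created if needed).
#' @param label file-name label, e.g. `"2012Q4"`.
#' @return named character vector of file paths, invisibly.
#' @export
write_faers_quarter <- function(tables, dir, label = "Q") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw_cols <- list(
    demo = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
             "reporter_country", "event_dt"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    ther = c("primaryid", "start_dt", "end_dt"),
    indi = c("primaryid", "indi_pt")
  )
  paths <- character(0)
  for (tab in names(raw_cols)) {
    df <- tables[[tab]]
    cols <- intersect(raw_cols[[tab]], names(df))
    df <- df[, cols, drop = FALSE]
    df[] <- lapply(df, function(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    })
    path <- file.path(dir, paste0(toupper(tab), label, ".txt"))
    lines <- c(paste(cols, collapse = "$"),
               do.call(paste, c(unname(as.list(df)), sep = "$")))
    if (!nrow(df)) lines <- lines[1]
    readr::write_lines(lines, path)
    paths[tab] <- path
  }
  invisible(paths)
}

#' Write a signal table
#'
#' Long-format export of signal results: one row per (drug, level, event,
#' context) with the 2x2 counts, expected count, shrunk ROR and IC with
#' their 95% lower bounds, and the significance flags. Values round-trip
#' through [read_signal_table()] at better than 10 significant digits.
#'
#' @param results tibble of signal results (as returned by
#'   [signal_scan()]); may be empty.
#' @param path output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_signal_table <- function(results, path) {
  cols <- c("drug", "level", "event", "context", "a", "b", "c", "d",
            "n_expected", "ror", "ror025", "ic", "ic025",
            "significant", "strong")
  missing <- setdiff(cols, names(results))
  if (length(missing)) {
    stop_pv("signal table is missing column(s): ", paste(missing, collapse = ", "))
  }
  out <- results[, c(cols, setdiff(names(results), cols)), drop = FALSE]
  writer <- if (grepl("\\.tsv$", path)) readr::write_tsv else readr::write_csv
  tryCatch(writer(out, path, progress = FALSE),
           error = function(e) stop_pv("cannot write signal table to ", path,
                                       ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a signal table written by [write_signal_table()]
#'
#' @param path file path (`.csv` or `.tsv`).
#' @return tibble of signal results.
#' @export
read_signal_table <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  reader(path, col_types = readr::cols(
    drug = readr::col_character(),
    level = readr::col_character(),
    event = readr::col_character(),
    context = readr::col_character(),
    a = readr::col_double(), b = readr::col_double(),
    c = readr::col_double(), d = readr::col_double(),
    n_expected = readr::col_double(),
    ror = readr::col_double(), ror025 = readr::col_double(),
    ic = readr::col_double(), ic025 = readr::col_double(),
    significant = readr::col_logical(), strong = readr::col_logical(),
    .default = readr::col_guess()
  ), progress = FALSE)
}
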