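# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Percentages in pharmacovigilance summary tables are conventionally
#' rounded half-up (so 42.645 prints as 42.65), unlike base R's
#' round-half-even. Used for every printed percentage in the package.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a total, rounded to two decimals
#'
#' @param n counts.
#' @param total denominator.
#' @return `n / total * 100` rounded half-up to 2 decimals.
#' @export
pct2 <- function(n, total) round_half_up(100 * n / total, 2)

# Canonical matching key: uppercase, strip everything but letters/digits.
# Collapses case, whitespace and punctuation variants of drug names and PTs.
norm_key <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[^A-Z0-9]+", "", x)
}

# Parse FAERS-style dates (YYYYMMDD, YYYYMM, YYYY). Returns a tibble with
# iso (string), num (sortable integer, partial dates padded with zeros)
# and precision in {day, month, year, missing}.
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == "" | !grepl("^[0-9]+$", x)] <- NA_character_
  nc <- nchar(x)
  precision <- dplyr::case_when(
    is.na(x) ~ "missing",
    nc == 8L ~ "day",
    nc == 6L ~ "month",
    nc == 4L ~ "year",
    TRUE ~ "missing"
  )
  x[precision == "missing"] <- NA_character_
  padded <- dplyr::case_when(
    precision == "day" ~ x,
    precision == "month" ~ paste0(x, "00"),
    precision == "year" ~ paste0(x, "0000"),
    TRUE ~ NA_character_
  )
  # reject impossible month/day fields
  mm <- suppressWarnings(as.integer(substr(padded, 5, 6)))
  dd <- suppressWarnings(as.integer(substr(padded, 7, 8)))
  bad <- !is.na(padded) & (mm > 12L | dd > 31L)
  padded[bad] <- NA_character_
  precision[bad] <- "missing"
  iso <- ifelse(
    is.na(padded), NA_character_,
    paste(substr(padded, 1, 4),
          ifelse(precision %in% c("day", "month"), substr(padded, 5, 6), "01"),
          ifelse(precision == "day", substr(padded, 7, 8), "01"),
          sep = "-")
  )
  tibble::tibble(
    iso = iso,
    num = suppressWarnings(as.integer(padded)),
    precision = precision
  )
}

# Convert FAERS (age, age_cod) pairs to years. Unit codes: DEC decades,
# YR years (also the assumption for a blank code), MON months, WK weeks,
# DY days, HR hours. Unparseable ages become NA.
harmonize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(as.character(age_cod)))
  cod[is.na(cod) | cod == ""] <- "YR"
  factor_tbl <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- unname(factor_tbl[cod])
  f[is.na(f)] <- NA_real_
  age * f
}

# ISO date string -> sortable integer YYYYMMDD
iso_to_num <- function(iso) {
  suppressWarnings(as.integer(gsub("-", "", iso)))
}

stop_pv <- function(...) rlang::abort(paste0(...), class = "pvsignal_error")
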