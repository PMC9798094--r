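# Independent scalar oracles and fixture builders. The oracle functions
# deliberately share no code with the package: plain scalar arithmetic
# transcribed from the formula definitions.

# Reference disproportionality statistics for one 2x2 table.
oracle_stats <- function(a, b, c, d) {
  n_drug <- a + b
  n_event <- a + c
  n_total <- a + b + c + d
  n_expected <- n_drug * n_event / n_total
  ror <- (a + 0.5) / (n_expected + 0.5)
  ic <- log(ror, base = 2)
  ic025 <- ic - 3.3 * (a + 0.5)^(-1 / 2) - 2 * (a + 0.5)^(-3 / 2)
  ror025 <- if (a > 0 && b > 0 && c > 0 && d > 0) {
    exp(log(ror) - 1.96 * sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  } else {
    NA_real_
  }
  list(n_expected = n_expected, ror = ror, ror025 = ror025,
       ic = ic, ic025 = ic025)
}

# Brute-force 2x2 counting over a list of reports, each a list with
# elements `drugs` (suspect ids) and `events`.
oracle_count <- function(reports, drug, event) {
  a <- b <- c <- d <- 0L
  for (r in reports) {
    has_d <- drug %in% r$drugs
    has_e <- event %in% r$events
    if (has_d && has_e) a <- a + 1L
    else if (has_d) b <- b + 1L
    else if (has_e) c <- c + 1L
    else d <- d + 1L
  }
  list(a = a, b = b, c = c, d = d)
}

# Write a set of FAERS-dialect tables to a temp dir and return the path
# list for read_faers_quarter(). Each argument is a character vector of
# pre-formatted $-delimited lines including the header.
write_quarter_lines <- function(demo = NULL, drug = NULL, reac = NULL,
                                outc = NULL, ther = NULL, indi = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  tabs <- list(demo = demo, drug = drug, reac = reac,
               outc = outc, ther = ther, indi = indi)
  paths <- list()
  for (tab in names(tabs)) {
    if (is.null(tabs[[tab]])) next
    p <- file.path(dir, paste0(toupper(tab), ".txt"))
    writeLines(tabs[[tab]], p)
    paths[[tab]] <- p
  }
  paths
}

# Build a preprocessed safety_reports object from a compact spec: a
# tibble with caseid, drug (suspect name), pts (list col), outcomes
# (list col, optional), plus optional comeds (list col of drug names).
make_reports <- function(spec, bundle = load_vocabulary()) {
  spec <- tibble::as_tibble(spec)
  n <- nrow(spec)
  if (!"outcomes" %in% names(spec)) spec$outcomes <- replicate(n, character(0), simplify = FALSE)
  if (!"comeds" %in% names(spec)) spec$comeds <- replicate(n, character(0), simplify = FALSE)
  pid <- as.character(1000 + seq_len(n))
  demo_lines <- c("primaryid$caseid$fda_dt$age$age_cod$sex$reporter_country$event_dt",
                  paste(pid, spec$caseid, "20150101", "50", "YR", "M", "US",
                        "20141201", sep = "$"))
  drug_lines <- c("primaryid$drug_seq$role_cod$drugname$prod_ai")
  reac_lines <- c("primaryid$pt")
  outc_lines <- c("primaryid$outc_cod")
  for (i in seq_len(n)) {
    drug_lines <- c(drug_lines,
                    paste(pid[i], "1", "PS", spec$drug[i], "", sep = "$"))
    for (cm in spec$comeds[[i]]) {
      drug_lines <- c(drug_lines, paste(pid[i], "2", "C", cm, "", sep = "$"))
    }
    for (pt in spec$pts[[i]]) {
      reac_lines <- c(reac_lines, paste(pid[i], pt, sep = "$"))
    }
    for (oc in spec$outcomes[[i]]) {
      outc_lines <- c(outc_lines, paste(pid[i], oc, sep = "$"))
    }
  }
  paths <- write_quarter_lines(demo = demo_lines, drug = drug_lines,
                               reac = reac_lines, outc = outc_lines)
  raw <- read_faers_quarter(paths)
  preprocess_reports(raw, bundle)
}

# Scenario used by the planted-signal recovery checks: five TAD targets,
# four comparator and forty background drugs, fifty IME events at 1%
# baseline, twelve pairs planted at lambda = 4, no injected defects.
recovery_scenario <- function(n_reports, bundle = load_vocabulary(),
                              lambda = 4) {
  tads <- sort(drugs_in_class(bundle, "TAD"))
  comps <- sort(drugs_in_class(bundle, "non-TAD-antifungal"))[1:4]
  bg <- sprintf("backgrounddrug%02d", 1:40)
  drugs <- tibble::tibble(
    drug = c(tads, comps, bg),
    prevalence = c(rep(0.02, 5), rep(0.015, 4),
                   rep((1 - 0.1 - 0.06) / 40, 40)),
    class = c(rep("TAD", 5), rep("non-TAD-antifungal", 4),
              rep("background", 40))
  )
  ime_pts <- bundle$pt_soc$pt[norm_key(bundle$pt_soc$pt) %in% bundle$ime_set]
  pts <- sort(ime_pts)[1:50]
  events <- classify_event(pts, bundle)
  events <- tibble::tibble(pt = events$pt, baseline = 0.01,
                           soc = events$soc, ime = events$ime)
  planted <- tibble::tibble(
    drug = rep(tads, times = c(4, 3, 2, 2, 1)),
    pt = pts[c(1, 5, 9, 13, 17, 21, 25, 29, 33, 37, 41, 45)],
    lambda = lambda
  )
  synthetic_scenario(n_reports = n_reports, drugs = drugs, events = events,
                     planted = planted, comed_probs = c(`0` = 1))
}

norm_key <- function(x) gsub("[^A-Z0-9]+", "", toupper(trimws(as.character(x))))
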