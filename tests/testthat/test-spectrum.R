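bundle <- load_vocabulary()

test_that("SOC analysis emits one row per observed SOC with dual AE/IME columns", {
  sr <- make_reports(tibble::tibble(
    caseid = as.character(1:8),
    drug = rep(c("FLUCONAZOLE", "OTHERDRUG"), each = 4),
    pts = list("Cholestasis", "Rash", "Headache", c("Cholestasis", "Rash"),
               "Rash", "Headache", "Cholestasis", "Rash")
  ), bundle)
  soc <- soc_analysis(sr, bundle, "fluconazole")
  expect_setequal(soc$soc, c("Hepatobiliary disorders",
                             "Skin and subcutaneous tissue disorders",
                             "Nervous system disorders"))
  expect_equal(nrow(soc), 3)
  # Rash and Headache are not IME: the IME pass only sees Cholestasis
  expect_equal(sum(soc$n_ime), sum(soc$n_ae[soc$soc == "Hepatobiliary disorders"]))
  # a SOC with a single IME report gets suppressed statistics
  one_ime <- soc[soc$soc == "Hepatobiliary disorders", ]
  expect_true(one_ime$n_ime < 3)
  expect_true(is.na(one_ime$ic025_ime))
})

test_that("a planted SOC excess flags only the planted drug-SOC pair", {
  socs <- c("Hepatobiliary disorders", "Cardiac disorders",
            "Renal and urinary disorders")
  pts <- c("Cholestasis", "Torsade de pointes", "Renal impairment",
           "Hepatitis", "Cardiac failure", "Acute kidney injury")
  ev <- classify_event(pts, bundle)
  events <- tibble::tibble(pt = pts, baseline = 0.02, soc = ev$soc, ime = ev$ime)
  drugs <- tibble::tibble(
    drug = c("voriconazole", sprintf("bg%02d", 1:20)),
    prevalence = c(0.05, rep(0.95 / 20, 20)),
    class = c("TAD", rep("background", 20)))
  planted <- tibble::tibble(drug = "voriconazole",
                            pt = c("Cholestasis", "Hepatitis"), lambda = 4)
  sc <- synthetic_scenario(n_reports = 3e4, drugs = drugs, events = events,
                           planted = planted)
  g <- generate_faers(sc, seed = 31)
  sr <- preprocess_reports(g$tables, bundle)
  soc <- soc_analysis(sr, bundle, "voriconazole")
  hep <- soc[soc$soc == "Hepatobiliary disorders", ]
  other <- soc[soc$soc %in% setdiff(socs, "Hepatobiliary disorders"), ]
  expect_true(hep$sig_ae)
  expect_true(all(!other$sig_ae))
})

test_that("the IME spectrum is min-case filtered, IME-restricted and ordered", {
  sr <- make_reports(tibble::tibble(
    caseid = as.character(1:12),
    drug = c(rep("VFEND", 6), rep("OTHERDRUG", 6)),
    pts = c(replicate(4, c("Cholestasis", "Rash"), simplify = FALSE),
            list("Delirium", "Delirium"),
            replicate(6, "Rash", simplify = FALSE))
  ), bundle)
  spec <- ime_spectrum(sr, bundle, c("voriconazole", "fluconazole"))
  # Rash is not IME; Delirium has only 2 cases; Cholestasis has 4
  expect_equal(spec$event, "Cholestasis")
  expect_equal(spec$a, 4)
  expect_true(all(spec$ime))
  # a drug with no IME PT reaching min_cases yields no rows
  expect_false("fluconazole" %in% spec$drug)
})

test_that("spectrum rows are invariant to report order", {
  set.seed(77)
  spec_tbl <- tibble::tibble(
    caseid = as.character(1:60),
    drug = sample(c("VFEND", "DIFLUCAN", "OTHERDRUG"), 60, TRUE),
    pts = replicate(60, sample(c("Cholestasis", "Delirium", "Sepsis", "Rash"),
                               sample(1:2, 1)), simplify = FALSE)
  )
  sr1 <- make_reports(spec_tbl, bundle)
  sr2 <- make_reports(spec_tbl[sample(60), ], bundle)
  s1 <- ime_spectrum(sr1, bundle, c("voriconazole", "fluconazole"))
  s2 <- ime_spectrum(sr2, bundle, c("voriconazole", "fluconazole"))
  expect_equal(as.data.frame(s1[, c("drug", "event", "a", "ic025")]),
               as.data.frame(s2[, c("drug", "event", "a", "ic025")]))
})

test_that("rendering honours top_n, keeps the full tidy table and is deterministic", {
  set.seed(9)
  n <- 40
  tab <- contingency_table(a = sample(5:60, n, TRUE), b = sample(50:200, n, TRUE),
                           c = sample(5:60, n, TRUE), d = 5000)
  res <- dplyr::bind_cols(
    tibble::tibble(drug = rep(c("drugA", "drugB"), each = 20),
                   level = "pt", context = "all-other-drugs",
                   event = rep(sprintf("Event %02d", 1:20), 2)),
    tab)
  res <- dplyr::bind_cols(
    res, tibble::tibble(ror = shrunk_ror(res), ror025 = ror_lower_bound(res)),
    information_component(res))
  res <- dplyr::bind_cols(res, classify_signal(res$ror025, res$a, res$ic025))
  res$soc <- "One SOC"
  res$ime <- TRUE

  f1 <- withr::local_tempfile(fileext = ".csv")
  out <- render_spectrum(res, top_n = 10, table_file = f1)
  expect_equal(nrow(out$table), n)
  expect_equal(sum(!is.na(out$table$display_rank)), min(10, sum(res$significant)))
  # ranking follows IC025 descending
  ranked <- dplyr::arrange(dplyr::filter(out$table, !is.na(display_rank)),
                           display_rank)
  expect_true(all(diff(ranked$ic025) <= 1e-12))
  # byte-identical re-render
  f2 <- withr::local_tempfile(fileext = ".csv")
  render_spectrum(res, top_n = 10, table_file = f2)
  expect_identical(readLines(f1), readLines(f2))
  # empty table: header-only tidy output, no figure, warning on file request
  empty <- res[0, ]
  f3 <- withr::local_tempfile(fileext = ".csv")
  expect_warning(out0 <- render_spectrum(empty, table_file = f3,
                                         file = withr::local_tempfile(fileext = ".png")),
                 "empty")
  expect_null(out0$figure)
  expect_equal(length(readLines(f3)), 1L)
})

test_that("a comparator class sharing the planted event weakens the signal", {
  # comparator drugs carry the planted event at elevated rate, so moving
  # from the all-other-drugs background to the comparator class must not
  # strengthen the signal
  pts <- c("Cholestasis", "Rash", "Sepsis")
  ev <- classify_event(pts, bundle)
  events <- tibble::tibble(pt = pts, baseline = 0.03, soc = ev$soc, ime = ev$ime)
  drugs <- tibble::tibble(
    drug = c("voriconazole", "amphotericin_b", "caspofungin",
             sprintf("bg%02d", 1:15)),
    prevalence = c(0.06, 0.05, 0.05, rep(0.84 / 15, 15)),
    class = c("TAD", "non-TAD-antifungal", "non-TAD-antifungal",
              rep("background", 15)))
  planted <- tibble::tibble(
    drug = c("voriconazole", "amphotericin_b", "caspofungin"),
    pt = "Cholestasis", lambda = c(5, 3, 3))
  sc <- synthetic_scenario(n_reports = 4e4, drugs = drugs, events = events,
                           planted = planted)
  g <- generate_faers(sc, seed = 99)
  sr <- preprocess_reports(g$tables, bundle)
  all_ctx <- signal_scan(sr, bundle, "voriconazole", level = "pt",
                         events = "Cholestasis")
  cls_ctx <- signal_scan(sr, bundle, "voriconazole", level = "pt",
                         events = "Cholestasis", context = "comparator-class",
                         comparators = c("amphotericin_b", "caspofungin"))
  expect_lte(cls_ctx$n_total, all_ctx$n_total)
  expect_lt(cls_ctx$ic025, all_ctx$ic025)
  expect_lt(cls_ctx$ic, all_ctx$ic)
})
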