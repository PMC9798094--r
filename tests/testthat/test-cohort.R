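bundle <- load_vocabulary()

test_that("cohort summaries tabulate sex, age, outcomes with half-up percentages", {
  sr <- make_reports(tibble::tibble(
    caseid = c("1", "2"),
    drug = "FLUCONAZOLE",
    pts = list("Rash", "Rash")
  ), bundle)
  # make case 2's sex unknown
  sr$cases$sex[sr$cases$caseid == "2"] <- "unknown"
  cs <- summarize_cohort(sr, bundle, "AE")
  expect_equal(cs$sex$pct[cs$sex$stratum == "M"], 50.00)
  expect_equal(cs$total, 2)
})

test_that("a 20-report fixture matches a hand tally", {
  spec <- tibble::tibble(
    caseid = as.character(1:20),
    drug = rep(c("FLUCONAZOLE", "VFEND"), each = 10),
    pts = c(replicate(8, "Cholestasis", simplify = FALSE),
            replicate(12, "Rash", simplify = FALSE)),
    outcomes = c(replicate(5, c("DE", "HO"), simplify = FALSE),
                 replicate(5, "OT", simplify = FALSE),
                 replicate(10, character(0), simplify = FALSE))
  )
  sr <- make_reports(spec, bundle)
  cs <- summarize_cohort(sr, bundle, "AE")
  expect_equal(cs$total, 20)
  # multi-outcome reports increment both categories
  expect_equal(cs$outcomes$n[cs$outcomes$code == "DE"], 5)
  expect_equal(cs$outcomes$n[cs$outcomes$code == "HO"], 5)
  expect_equal(cs$outcomes$n[cs$outcomes$code == "OT"], 5)
  expect_equal(cs$outcomes$pct[cs$outcomes$code == "DE"], 25.00)
  # IME cohort: the 8 cholestasis reports
  ime <- summarize_cohort(sr, bundle, "IME")
  expect_equal(ime$total, 8)
  # distinct-report serious count under strict4: 5 reports carry DE/HO
  expect_equal(serious_outcome_count(cs, "strict4"), 5)
  expect_equal(serious_outcome_count(cs, "nonhosp5"), 5)
})

test_that("serious counts obey the subset relation and the brute-force rule", {
  set.seed(12)
  codes <- names(outcome_code_map())
  spec <- tibble::tibble(
    caseid = as.character(1:50),
    drug = "FLUCONAZOLE",
    pts = replicate(50, "Rash", simplify = FALSE),
    outcomes = replicate(50, codes[runif(7) < 0.3], simplify = FALSE)
  )
  sr <- make_reports(spec, bundle)
  cs <- summarize_cohort(sr, bundle, "AE")
  for (def in c("strict4", "nonhosp5")) {
    want <- sum(vapply(spec$outcomes, function(s) {
      outcome_severity(s, def)$serious
    }, logical(1)))
    expect_equal(serious_outcome_count(cs, def), want)
  }
  n_de <- sum(vapply(spec$outcomes, function(s) "DE" %in% s, logical(1)))
  expect_gte(serious_outcome_count(cs, "strict4"), n_de)
})

test_that("drug-wise shares reproduce count/total arithmetic", {
  sr <- make_reports(tibble::tibble(
    caseid = as.character(1:10),
    drug = c(rep("FLUCONAZOLE", 6), rep("VFEND", 4)),
    pts = c(replicate(6, "Cholestasis", simplify = FALSE),
            replicate(4, "Rash", simplify = FALSE))
  ), bundle)
  sh <- drugwise_share(sr, bundle, c("fluconazole", "voriconazole"))
  expect_equal(sh$pct_ae, c(60.00, 40.00))
  expect_equal(sum(sh$pct_ae), 100)
  # IME cohort contains only the cholestasis reports
  expect_equal(sh$pct_ime, c(100.00, 0.00))
  one <- drugwise_share(sr, bundle, "fluconazole")
  expect_equal(one$pct_ae, 100.00)
})

test_that("comedication bins partition reports and a lone drug lands in bin 0", {
  sr <- make_reports(tibble::tibble(
    caseid = as.character(1:4),
    drug = "FLUCONAZOLE",
    pts = list("Cholestasis", "Rash", "Rash", "Rash"),
    comeds = list(character(0), "RIFAMPIN",
                  c("RIFAMPIN", "OMEPRAZOLE", "ASPIRIN"),
                  c("A1", "A2", "A3", "A4", "A5", "A6", "A7"))
  ), bundle)
  grid <- comedication_incidence(sr, bundle, "fluconazole")
  expect_equal(sum(grid$n_ae), 4)
  expect_equal(grid$n_ae[grid$bin == "0"], 1)
  expect_equal(grid$n_ae[grid$bin == "1"], 1)
  expect_equal(grid$n_ae[grid$bin == "3"], 1)
  expect_equal(grid$n_ae[grid$bin == ">5"], 1)
  expect_equal(grid$incidence[grid$bin == "0"], 100.00)  # cholestasis is IME
  # absent drug: zero row, incidence undefined
  gz <- comedication_incidence(sr, bundle, "isavuconazole")
  expect_true(all(gz$n_ae == 0))
  expect_true(all(is.na(gz$incidence)))
})

test_that("IME incidence rises with comedication count when the generator plants a slope", {
  sc <- default_scenario(n_reports = 4e4, bundle = bundle, n_events = 40)
  sc$comed_ime_slope <- 0.30
  g <- generate_faers(sc, seed = 55)
  sr <- preprocess_reports(g$tables, bundle)
  grid <- comedication_incidence(sr, bundle, drugs_in_class(bundle, "TAD"))
  pooled <- grid |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(inc = 100 * sum(n_ime) / sum(n_ae), n = sum(n_ae))
  # pooled incidence in the well-populated low bins is monotone increasing
  low <- pooled[pooled$n > 100, ]
  expect_gt(nrow(low), 2)
  expect_true(all(diff(low$inc) > 0))
})

test_that("the outcome-by-PT cross-tab uses the grand total as denominator", {
  spec <- tibble::tibble(
    caseid = as.character(1:6),
    drug = "VFEND",
    pts = list("Cholestasis", "Cholestasis", "Renal impairment",
               c("Cholestasis", "Renal impairment"), "Rash", "Rash"),
    outcomes = list("DE", c("DE", "HO"), "HO", "OT", "DE", character(0))
  )
  sr <- make_reports(spec, bundle)
  xt <- significant_ime_outcomes(sr, bundle)
  # hand tally of (report, category, PT) records among PT-carrying reports:
  # DE-Cholestasis 2 (cases 1,2), HO-Cholestasis 1 (case 2),
  # HO-Renal 1 (case 3), OT unlisted 2 (case 4 x both PTs) -> grand 6
  expect_equal(attr(xt, "grand_total"), 6)
  expect_equal(xt$records[xt$outcome == "DE" & xt$pt == "Cholestasis"], 2)
  expect_equal(xt$records[xt$outcome == "HO" & xt$pt == "Renal impairment"], 1)
  expect_equal(xt$records[xt$outcome == "(unlisted)"], 2)
  expect_equal(xt$pct[xt$outcome == "DE" & xt$pt == "Cholestasis"], 33.33)
  # single report, single PT, one outcome: 100% of listed records
  sr1 <- make_reports(tibble::tibble(
    caseid = "1", drug = "VFEND", pts = list("Cholestasis"),
    outcomes = list("HO")), bundle)
  xt1 <- significant_ime_outcomes(sr1, bundle)
  expect_equal(nrow(xt1), 1)
  expect_equal(xt1$pct, 100)
})
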