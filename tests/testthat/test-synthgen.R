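bundle <- load_vocabulary()

test_that("generation is byte-reproducible under a fixed seed", {
  sc <- default_scenario(n_reports = 800, bundle = bundle, seed = 17)
  g1 <- generate_faers(sc, seed = 17)
  g2 <- generate_faers(sc, seed = 17)
  for (tab in c("demo", "drug", "reac", "outc")) {
    expect_identical(g1$tables[[tab]], g2$tables[[tab]])
  }
  g3 <- generate_faers(sc, seed = 18)
  expect_false(identical(g1$tables$demo, g3$tables$demo))
})

test_that("every generated report carries at least one reaction", {
  sc <- default_scenario(n_reports = 2000, bundle = bundle, n_events = 20)
  g <- generate_faers(sc, seed = 3)
  expect_setequal(unique(g$tables$reac$primaryid),
                  unique(g$tables$demo$primaryid))
})

test_that("injected duplicates and defects are recovered exactly from the truth record", {
  sc <- default_scenario(n_reports = 1000, bundle = bundle)
  sc$duplicate_rate <- 0.2
  g <- generate_faers(sc, seed = 41)
  truth <- g$truth
  expect_equal(length(truth$duplicate_caseids), 200)
  sr <- deduplicate(as_safety_reports(g$tables))
  att <- attrition_log(sr)
  # dedup removes the injected duplicates plus the sex-conflict extras
  expect_equal(att$n_removed[att$stage == "dedup"],
               length(truth$duplicate_caseids) +
                 length(truth$sex_conflict_caseids))
  sr <- quality_filter(deduplicate(as_safety_reports(g$tables)))
  expect_equal(nrow(sr$cases), truth$expected_after_filter)
  qf <- attrition_log(sr)
  expect_equal(qf$n_removed[qf$rule == "age > 150"],
               length(truth$age_defect_caseids))
  expect_equal(qf$n_removed[qf$rule == "sex conflict across submissions"],
               length(truth$sex_conflict_caseids))
  expect_equal(qf$n_removed[qf$rule == "fda_dt outside analysis window"],
               length(truth$date_defect_caseids))
  # the removed caseids are exactly the injected ones
  expect_true(!any(truth$age_defect_caseids %in% sr$cases$caseid))
  expect_true(!any(truth$sex_conflict_caseids %in% sr$cases$caseid))
  expect_true(!any(truth$date_defect_caseids %in% sr$cases$caseid))
})

test_that("a clean scenario suffers zero attrition", {
  sc <- default_scenario(n_reports = 100, bundle = bundle)
  sc$duplicate_rate <- 0
  sc$defect_rates <- list(age = 0, sex = 0, date = 0)
  g <- generate_faers(sc, seed = 1)
  sr <- preprocess_reports(g$tables, bundle)
  expect_equal(nrow(sr$cases), 100)
  expect_equal(sum(attrition_log(sr)$n_removed), 0)
})

test_that("a planted multiplier is recovered as an observed/expected ratio", {
  sc <- recovery_scenario(1e5, bundle)
  pair <- sc$planted[1, ]
  g <- generate_faers(sc, seed = 8)
  sr <- preprocess_reports(g$tables, bundle)
  tab <- build_contingency(sr, bundle, pair$drug, pair$pt, level = "pt")
  rr <- tab$a / tab$n_expected
  expect_gt(rr, 3.5)
  expect_lt(rr, 4.5)
})

test_that("the analytic expected IC matches its limiting cases", {
  drugs <- tibble::tibble(drug = c("target", sprintf("bg%02d", 1:30)),
                          prevalence = c(0.01, rep(0.99 / 30, 30)),
                          class = c("TAD", rep("background", 30)))
  pts <- bundle$pt_soc$pt[1:40]
  ev <- classify_event(pts, bundle)
  events <- tibble::tibble(pt = ev$pt, baseline = 0.05, soc = ev$soc,
                           ime = ev$ime)
  mk <- function(lambda) {
    synthetic_scenario(
      n_reports = 1e6, drugs = drugs, events = events,
      planted = tibble::tibble(drug = "target", pt = pts[1], lambda = lambda))
  }
  # lambda = 1: no association, expected IC essentially zero
  expect_lt(abs(expected_ic(mk(1), "target", pts[1])), 0.02)
  # lambda = 4 with negligible margin contamination: about 2 bits
  expect_lt(abs(expected_ic(mk(4), "target", pts[1]) - 2), 0.25)
})

test_that("expected IC matches a Monte-Carlo estimate under margin contamination", {
  # a prevalent target drug contaminates the event margin; the analytic
  # value must track the simulation, not log2(lambda)
  drugs <- tibble::tibble(drug = c("target", sprintf("bg%02d", 1:10)),
                          prevalence = c(0.30, rep(0.70 / 10, 10)),
                          class = c("TAD", rep("background", 10)))
  pts <- bundle$pt_soc$pt[1:10]
  ev <- classify_event(pts, bundle)
  events <- tibble::tibble(pt = ev$pt, baseline = 0.05, soc = ev$soc,
                           ime = ev$ime)
  sc <- synthetic_scenario(
    n_reports = 2e5, drugs = drugs, events = events,
    planted = tibble::tibble(drug = "target", pt = pts[1], lambda = 2))
  want <- expected_ic(sc, "target", pts[1])
  expect_lt(want, log2(2))  # contamination shrinks the apparent signal
  g <- generate_faers(sc, seed = 12)
  sr <- preprocess_reports(g$tables, bundle)
  got <- signal_scan(sr, bundle, "target", level = "pt", events = pts[1])$ic
  expect_lt(abs(got - want), 0.1)
})

test_that("scenario validation rejects bad inputs and clamps infeasible probabilities", {
  drugs <- tibble::tibble(drug = "d1", prevalence = 1, class = "TAD")
  events <- tibble::tibble(pt = "Cholestasis", baseline = 0.6,
                           soc = "Hepatobiliary disorders", ime = TRUE)
  expect_error(synthetic_scenario(10, drugs, events, duplicate_rate = 1),
               "duplicate_rate")
  expect_error(synthetic_scenario(
    10, drugs, events,
    planted = tibble::tibble(drug = "nope", pt = "Cholestasis", lambda = 2)),
    "unknown")
  expect_warning(synthetic_scenario(
    10, drugs, events,
    planted = tibble::tibble(drug = "d1", pt = "Cholestasis", lambda = 2)),
    "clamped")
})
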