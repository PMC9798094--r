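# Synthetic FAERS-like data with known ground truth. Reports are drawn
# from an explicit generative model -- suspect drug, comedication count,
# per-(drug,event) inclusion probabilities with planted multipliers,
# outcome codes conditional on IME presence -- then duplicates and
# quality defects are injected post-hoc on sampled clean reports so the
# truth record can state exact expected attrition.

#' Define a synthetic reporting scenario
#'
#' @param n_reports number of distinct cases to generate.
#' @param drugs tibble with columns `drug` (canonical id), `prevalence`
#'   (suspect-drug marginal, normalized internally), `class` (`"TAD"`,
#'   `"non-TAD-antifungal"` or `"background"`); an optional list-column
#'   `synonyms` supplies reported-name variants per drug.
#' @param events tibble with columns `pt`, `baseline` (per-report
#'   inclusion probability), `soc`, `ime` (logical).
#' @param planted tibble with columns `drug`, `pt`, `lambda`; a
#'   multiplier `lambda` scales the baseline inclusion probability of
#'   that pair (`lambda = 1` plants nothing, `lambda = 0` suppresses the
#'   pair). Pairs not listed have `lambda = 1`.
#' @param duplicate_rate fraction of cases receiving an extra earlier
#'   submission that deduplication must remove.
#' @param defect_rates list with fractions `age` (age set above 150),
#'   `sex` (a conflicting-sex extra submission), `date` (fda_dt moved
#'   before the analysis window); defect sets are disjoint.
#' @param comed_probs probability vector over comedication counts
#'   0, 1, 2, ... (normalized internally).
#' @param comed_ime_slope relative increase of each IME event's
#'   inclusion probability per added comedication (0.05 = 5% per drug).
#' @param outcome_probs list of two named vectors `base` and `ime`:
#'   per-category outcome probabilities for reports without/with an IME
#'   event.
#' @param filler_pts character vector of nonspecific PTs assigned (one,
#'   uniformly) to reports whose independent event draws all miss, so
#'   that every report carries a reaction without perturbing the scored
#'   events' margins.
#' @param window dates (ISO strings) between which clean `fda_dt` values
#'   are drawn.
#' @param seed default seed used by [generate_faers()] when none is
#'   passed.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_reports, drugs, events,
                               planted = NULL,
                               duplicate_rate = 0,
                               defect_rates = list(age = 0, sex = 0, date = 0),
                               comed_probs = c(`0` = 1),
                               comed_ime_slope = 0,
                               outcome_probs = list(
                                 base = c(DE = 0.10, LT = 0.02, HO = 0.20,
                                          DS = 0.01, CA = 0.002, RI = 0.001,
                                          OT = 0.40),
                                 ime = c(DE = 0.30, LT = 0.05, HO = 0.33,
                                         DS = 0.02, CA = 0.004, RI = 0.002,
                                         OT = 0.60)),
                               filler_pts = sprintf("Nonspecific symptom %02d",
                                                    1:10),
                               window = c("2013-01-01", "2022-03-31"),
                               seed = 1L) {
  drugs <- tibble::as_tibble(drugs)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("drug", "prevalence", "class") %in% names(drugs)),
            all(c("pt", "baseline", "soc", "ime") %in% names(events)),
            n_reports >= 1)
  if (anyDuplicated(drugs$drug)) stop_pv("duplicate drug ids in scenario")
  if (anyDuplicated(events$pt)) stop_pv("duplicate event PTs in scenario")
  if (any(events$baseline < 0 | events$baseline > 1)) {
    stop_pv("event baselines must be probabilities")
  }
  if (duplicate_rate < 0 || duplicate_rate >= 1) {
    stop_pv("duplicate_rate must be in [0, 1)")
  }
  for (nm in c("age", "sex", "date")) {
    if (is.null(defect_rates[[nm]])) defect_rates[[nm]] <- 0
  }
  if (is.null(planted)) {
    planted <- tibble::tibble(drug = character(), pt = character(),
                              lambda = numeric())
  }
  planted <- tibble::as_tibble(planted)
  bad <- !planted$drug %in% drugs$drug | !planted$pt %in% events$pt
  if (any(bad)) stop_pv("planted pairs reference unknown drugs/events")
  if (any(planted$lambda < 0)) stop_pv("lambda must be >= 0")
  clamped <- planted$lambda *
    events$baseline[match(planted$pt, events$pt)] > 1
  if (any(clamped)) {
    rlang::warn(paste(sum(clamped),
      "planted pair(s) exceed probability 1 and are clamped"))
  }
  drugs$prevalence <- drugs$prevalence / sum(drugs$prevalence)
  if (!"synonyms" %in% names(drugs)) {
    drugs$synonyms <- lapply(toupper(drugs$drug), identity)
  }
  comed_probs <- comed_probs / sum(comed_probs)
  filler_pts <- setdiff(filler_pts, events$pt)
  if (!length(filler_pts)) stop_pv("filler_pts must not all be scored events")
  structure(list(
    n_reports = as.integer(n_reports), drugs = drugs, events = events,
    planted = planted, duplicate_rate = duplicate_rate,
    defect_rates = defect_rates, comed_probs = comed_probs,
    comed_ime_slope = comed_ime_slope, outcome_probs = outcome_probs,
    filler_pts = filler_pts, window = window, seed = as.integer(seed)
  ), class = "synthetic_scenario")
}

#' Default scenario shaped like a triazole-antifungal surveillance study
#'
#' Five TAD target drugs, four non-TAD antifungal comparators and forty
#' background drugs; events drawn from the shipped mock vocabulary (27
#' SOCs, roughly half IME); a decaying comedication-count distribution
#' with a 5% IME-risk increase per added drug; small duplicate and
#' defect rates.
#'
#' @param n_reports number of cases (default 10000).
#' @param bundle vocabulary bundle supplying drugs and PTs.
#' @param n_events number of event PTs (sampled deterministically as the
#'   first `n_events` of the vocabulary, alternating IME and non-IME).
#' @param planted optional planted-pair tibble (see
#'   [synthetic_scenario()]).
#' @param ... further arguments to [synthetic_scenario()].
#' @return a `synthetic_scenario`.
#' @export
default_scenario <- function(n_reports = 10000, bundle = load_vocabulary(),
                             n_events = 60, planted = NULL, ...) {
  tads <- drugs_in_class(bundle, "TAD")
  comps <- drugs_in_class(bundle, "non-TAD-antifungal")[1:4]
  bg <- sprintf("backgrounddrug%02d", 1:40)
  drugs <- tibble::tibble(
    drug = c(tads, comps, bg),
    prevalence = c(rep(0.02, length(tads)), rep(0.015, length(comps)),
                   rep((1 - 0.02 * length(tads) - 0.015 * length(comps)) / 40,
                       40)),
    class = c(rep("TAD", length(tads)), rep("non-TAD-antifungal", length(comps)),
              rep("background", 40))
  )
  syn <- split(bundle$synonyms$raw_name, bundle$synonyms$canonical)
  drugs$synonyms <- lapply(drugs$drug, function(d) {
    if (!is.null(syn[[d]])) syn[[d]] else toupper(d)
  })
  cls <- classify_event(bundle$pt_soc$pt, bundle)
  cls <- dplyr::bind_rows(cls[cls$ime, ], cls[!cls$ime, ])
  idx <- as.vector(rbind(seq_len(nrow(cls) / 2),
                         nrow(cls) / 2 + seq_len(nrow(cls) / 2)))
  idx <- idx[idx <= nrow(cls)]
  cls <- cls[idx, ][seq_len(min(n_events, nrow(cls))), ]
  if (!is.null(planted)) {
    extra <- setdiff(unique(planted$pt), cls$pt)
    if (length(extra)) cls <- dplyr::bind_rows(cls, classify_event(extra, bundle))
  }
  events <- tibble::tibble(pt = cls$pt, baseline = 0.01, soc = cls$soc,
                           ime = cls$ime)
  # filler reactions for otherwise event-free reports: common non-IME
  # vocabulary PTs that are not scored events
  leftover <- classify_event(setdiff(bundle$pt_soc$pt, events$pt), bundle)
  filler <- utils::head(leftover$pt[!leftover$ime], 15)
  if (length(filler) < 5) filler <- sprintf("Nonspecific symptom %02d", 1:10)
  synthetic_scenario(
    n_reports = n_reports, drugs = drugs, events = events, planted = planted,
    filler_pts = filler,
    duplicate_rate = 0.02,
    defect_rates = list(age = 0.005, sex = 0.005, date = 0.01),
    comed_probs = setNames(0.55 * 0.55^(0:7) / sum(0.55^(0:7)) +
                             c(0.45, rep(0, 7)), 0:7),
    comed_ime_slope = 0.05, ...
  )
}

# lambda lookup matrix (drugs x events)
lambda_matrix <- function(scenario) {
  L <- matrix(1, nrow(scenario$drugs), nrow(scenario$events),
              dimnames = list(scenario$drugs$drug, scenario$events$pt))
  if (nrow(scenario$planted)) {
    L[cbind(match(scenario$planted$drug, scenario$drugs$drug),
            match(scenario$planted$pt, scenario$events$pt))] <-
      scenario$planted$lambda
  }
  L
}

# inclusion probability matrix for one comedication count m
prob_matrix <- function(scenario, m) {
  L <- lambda_matrix(scenario)
  base <- matrix(scenario$events$baseline, nrow(scenario$drugs),
                 nrow(scenario$events), byrow = TRUE)
  boost <- 1 + scenario$comed_ime_slope * m *
    matrix(scenario$events$ime, nrow(scenario$drugs),
           nrow(scenario$events), byrow = TRUE)
  pmin(L * base * boost, 1)
}

#' Generate a synthetic FAERS-like quarter set
#'
#' Draws `n_reports` cases from the scenario's generative model, then
#' injects duplicate submissions and quality defects on disjoint sampled
#' subsets. Every report carries at least one reaction PT: a report
#' whose independent event draws all miss receives one nonspecific
#' filler PT, which keeps the scored events' margins exactly binomial.
#' Output is byte-reproducible given the seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed integer seed; default the scenario's.
#' @return list with `tables` (a `faers_tables` object) and `truth`
#'   (planted pairs, injected caseid sets, per-report IME presence and
#'   comedication counts, and expected post-stage report counts).
#' @export
generate_faers <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(seed)
  n <- scenario$n_reports
  D <- nrow(scenario$drugs)
  E <- nrow(scenario$events)
  drug_idx <- sample.int(D, n, replace = TRUE,
                         prob = scenario$drugs$prevalence)
  m_support <- as.integer(names(scenario$comed_probs))
  if (!length(m_support)) m_support <- seq_along(scenario$comed_probs) - 1L
  m <- sample(m_support, n, replace = TRUE, prob = scenario$comed_probs)

  # event draws, grouped by (drug, comedication count); accumulate in
  # lists to stay linear in the number of event rows
  acc_rep <- list()
  acc_evt <- list()
  groups <- split(seq_len(n), list(drug = drug_idx, m = m), drop = TRUE)
  for (g in groups) {
    d <- drug_idx[g[1]]
    P <- prob_matrix(scenario, m[g[1]])[d, ]
    for (e in seq_len(E)) {
      if (P[e] <= 0) next
      k <- rbinom(1, length(g), P[e])
      if (k > 0) {
        hit <- if (length(g) == 1) g else sample(g, k)
        acc_rep[[length(acc_rep) + 1L]] <- hit
        acc_evt[[length(acc_evt) + 1L]] <- rep.int(e, k)
      }
    }
  }
  ev_report <- unlist(acc_rep, use.names = FALSE)
  ev_event <- unlist(acc_evt, use.names = FALSE)
  if (is.null(ev_report)) {
    ev_report <- integer(0)
    ev_event <- integer(0)
  }
  # filler PT for reports with no scored event: keeps the invariant
  # "every report has a reaction" without touching scored-event margins
  n_ev <- tabulate(ev_report, nbins = n)
  empty <- which(n_ev == 0L)
  filler <- sample(scenario$filler_pts, length(empty), replace = TRUE)
  ord <- order(ev_report, ev_event)
  ev_report <- ev_report[ord]
  ev_event <- ev_event[ord]

  has_ime <- rep(FALSE, n)
  ime_rows <- scenario$events$ime[ev_event]
  has_ime[unique(ev_report[ime_rows])] <- TRUE

  # outcomes per report
  op <- scenario$outcome_probs
  codes <- names(op$base)
  oc_report <- integer(0)
  oc_code <- character(0)
  for (code in codes) {
    p <- ifelse(has_ime, op$ime[[code]], op$base[[code]])
    hit <- which(runif(n) < p)
    oc_report <- c(oc_report, hit)
    oc_code <- c(oc_code, rep(code, length(hit)))
  }

  # demographics; primaryid = caseid || version, numeric to avoid
  # 32-bit overflow
  caseid <- 90000000 + seq_len(n)
  primaryid <- caseid * 10 + 2
  age <- round(pmax(0, pmin(102, rnorm(n, 60, 17))))
  age_missing <- runif(n) < 0.30
  sex <- sample(c("M", "F", "UNK"), n, replace = TRUE,
                prob = c(0.48, 0.39, 0.13))
  country <- sample(c("US", "JP", "FR", "CN", "GB", "DE", "IT"), n,
                    replace = TRUE,
                    prob = c(0.54, 0.09, 0.08, 0.07, 0.08, 0.08, 0.06))
  d0 <- as.Date(scenario$window[1])
  d1 <- as.Date(scenario$window[2])
  fda_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, replace = TRUE) - 1L
  event_date <- fda_date - sample.int(180L, n, replace = TRUE)

  # disjoint defect/duplicate index sets
  n_dup <- floor(scenario$duplicate_rate * n)
  n_age <- floor(scenario$defect_rates$age * n)
  n_sex <- floor(scenario$defect_rates$sex * n)
  n_date <- floor(scenario$defect_rates$date * n)
  pick <- sample.int(n, n_dup + n_age + n_sex + n_date)
  idx_dup <- pick[seq_len(n_dup)]
  idx_age <- pick[n_dup + seq_len(n_age)]
  idx_sex <- pick[n_dup + n_age + seq_len(n_sex)]
  idx_date <- pick[n_dup + n_age + n_sex + seq_len(n_date)]
  if (n_age) {
    age[idx_age] <- sample(151:210, n_age, replace = TRUE)
    age_missing[idx_age] <- FALSE
  }
  if (n_sex) sex[idx_sex] <- "M"  # conflicting duplicate will say F
  if (n_date) {
    fda_date[idx_date] <- as.Date("2009-01-01") +
      sample.int(1000L, n_date, replace = TRUE)
  }

  fmt_dt <- function(d) format(d, "%Y%m%d")
  demo <- tibble::tibble(
    primaryid = as.character(primaryid),
    caseid = as.character(caseid),
    fda_dt = fmt_dt(fda_date),
    age = ifelse(age_missing, "", as.character(age)),
    age_cod = ifelse(age_missing, "", "YR"),
    sex = sex,
    reporter_country = country,
    event_dt = fmt_dt(event_date)
  )

  # extra submissions: duplicates (same sex) and sex-conflict injections
  extra_idx <- c(idx_dup, idx_sex)
  if (length(extra_idx)) {
    extra <- demo[extra_idx, ]
    extra$primaryid <- as.character(caseid[extra_idx] * 10 + 1)
    extra$fda_dt <- fmt_dt(fda_date[extra_idx] -
                             sample.int(300L, length(extra_idx), replace = TRUE))
    if (length(idx_sex)) {
      # conflicting sex on the injected earlier submission
      extra$sex[length(idx_dup) + seq_along(idx_sex)] <- "F"
    }
    demo <- dplyr::bind_rows(demo, extra)
  }

  # drug mentions: one suspect + m distinct comedications
  syn_pool <- scenario$drugs$synonyms
  pick_name <- function(di) {
    pool <- syn_pool[[di]]
    pool[sample.int(length(pool), 1L)]
  }
  suspect_name <- vapply(drug_idx, pick_name, character(1))
  jitter <- runif(n) < 0.1
  suspect_name[jitter] <- paste0(" ", tolower(suspect_name[jitter]))
  com_report <- rep(seq_len(n), m)
  if (length(com_report)) {
    com_drug <- sample.int(D, length(com_report), replace = TRUE)
    for (iter in 1:25) {
      clash <- com_drug == drug_idx[com_report] |
        duplicated(paste0(com_report, "_", com_drug))
      if (!any(clash)) break
      com_drug[clash] <- sample.int(D, sum(clash), replace = TRUE)
    }
    com_name <- vapply(com_drug, pick_name, character(1))
    com_role <- sample(c("C", "SS", "I"), length(com_report), replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
  } else {
    com_drug <- integer(0); com_name <- character(0); com_role <- character(0)
  }
  drug_tbl <- dplyr::bind_rows(
    tibble::tibble(primaryid = as.character(primaryid),
                   caseid_int = caseid,
                   drug_seq = "1", role_cod = "PS",
                   drugname = suspect_name,
                   prod_ai = toupper(scenario$drugs$drug[drug_idx])),
    tibble::tibble(primaryid = as.character(primaryid[com_report]),
                   caseid_int = caseid[com_report],
                   drug_seq = as.character(1L + stats::ave(
                     com_report, com_report, FUN = seq_along)),
                   role_cod = com_role,
                   drugname = com_name,
                   prod_ai = toupper(scenario$drugs$drug[com_drug]))
  )

  reac_tbl <- dplyr::bind_rows(
    tibble::tibble(
      primaryid = as.character(primaryid[ev_report]),
      caseid_int = caseid[ev_report],
      pt = scenario$events$pt[ev_event]
    ),
    tibble::tibble(
      primaryid = as.character(primaryid[empty]),
      caseid_int = caseid[empty],
      pt = filler
    )
  )
  outc_tbl <- tibble::tibble(
    primaryid = as.character(primaryid[oc_report]),
    caseid_int = caseid[oc_report],
    outc_cod = oc_code
  )
  # children rows mirrored for extra submissions
  if (length(extra_idx)) {
    mirror <- function(df) {
      sub <- df[df$caseid_int %in% caseid[extra_idx], ]
      sub$primaryid <- as.character(
        as.numeric(sub$primaryid) - 1)  # *10+2 -> *10+1
      sub
    }
    drug_tbl <- dplyr::bind_rows(drug_tbl, mirror(drug_tbl))
    reac_tbl <- dplyr::bind_rows(reac_tbl, mirror(reac_tbl))
    outc_tbl <- dplyr::bind_rows(outc_tbl, mirror(outc_tbl))
  }
  drop_int <- function(df) dplyr::select(df, -dplyr::all_of("caseid_int"))

  ther_tbl <- tibble::tibble(
    primaryid = as.character(primaryid),
    start_dt = fmt_dt(event_date - 30L),
    end_dt = fmt_dt(event_date)
  )
  indi_tbl <- tibble::tibble(
    primaryid = as.character(primaryid),
    indi_pt = sample(c("Fungal infection", "Candida infection",
                       "Aspergillus infection", "Antifungal prophylaxis"),
                     n, replace = TRUE)
  )

  raw <- structure(list(
    demo = postprocess_faers_table("demo", demo),
    drug = postprocess_faers_table("drug", drop_int(drug_tbl)),
    reac = postprocess_faers_table("reac", drop_int(reac_tbl)),
    outc = postprocess_faers_table("outc", drop_int(outc_tbl)),
    ther = postprocess_faers_table("ther", ther_tbl),
    indi = postprocess_faers_table("indi", indi_tbl),
    manifest = tibble::tibble(), quarter_label = "synthetic"
  ), class = "faers_tables")

  truth <- list(
    seed = seed,
    planted = scenario$planted,
    duplicate_caseids = as.character(caseid[idx_dup]),
    sex_conflict_caseids = as.character(caseid[idx_sex]),
    age_defect_caseids = as.character(caseid[idx_age]),
    date_defect_caseids = as.character(caseid[idx_date]),
    n_reports = n,
    n_submissions = n + length(extra_idx),
    expected_after_dedup = n,
    expected_after_filter = n - n_age - n_sex - n_date,
    report_drug = tibble::tibble(caseid = as.character(caseid),
                                 drug = scenario$drugs$drug[drug_idx],
                                 comed_count = m,
                                 has_ime = has_ime)
  )
  list(tables = raw, truth = truth)
}

#' Analytic expected information component under a scenario
#'
#' Expected IC (bits) for a drug--event pair, accounting for the
#' generator's full event model: the planted multiplier, the
#' comedication-dependent IME boost averaged over the comedication
#' distribution, and the target drug's own contribution to the event
#' margin. For a pair with negligible margin contamination this
#' approaches `log2(lambda)`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param drug,event canonical drug id and event PT.
#' @param context `"all-other-drugs"` or `"comparator-class"`.
#' @return expected IC in bits.
#' @export
expected_ic <- function(scenario, drug, event,
                        context = c("all-other-drugs", "comparator-class")) {
  context <- match.arg(context)
  di <- match(drug, scenario$drugs$drug)
  ei <- match(event, scenario$events$pt)
  if (is.na(di) || is.na(ei)) stop_pv("unknown drug or event")
  m_support <- as.integer(names(scenario$comed_probs))
  w <- unname(scenario$comed_probs)
  # q[d, e]: P(report of drug d contains event e), averaged over the
  # comedication distribution (filler PTs never touch scored events)
  q <- matrix(0, nrow(scenario$drugs), nrow(scenario$events))
  for (j in seq_along(m_support)) {
    q <- q + w[j] * prob_matrix(scenario, m_support[j])
  }
  keep <- if (context == "all-other-drugs") {
    seq_len(nrow(scenario$drugs))
  } else {
    which(scenario$drugs$drug == drug |
            scenario$drugs$class == "non-TAD-antifungal")
  }
  prev <- scenario$drugs$prevalence[keep] / sum(scenario$drugs$prevalence[keep])
  n_eff <- scenario$n_reports *
    (1 - scenario$defect_rates$age - scenario$defect_rates$sex -
       scenario$defect_rates$date)
  if (context == "comparator-class") {
    n_eff <- n_eff * sum(scenario$drugs$prevalence[keep])
  }
  ki <- match(di, keep)
  ea <- n_eff * prev[ki] * q[di, ei]
  e_drug <- n_eff * prev[ki]
  e_event <- n_eff * sum(prev * q[keep, ei])
  e_exp <- e_drug * e_event / n_eff
  log2((ea + 0.5) / (e_exp + 0.5))
}
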