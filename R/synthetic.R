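# Synthetic FAERS generator: seven-table file sets with controlled statistical
# structure (Zipf marginals, implanted drug-event signals, duplicate caseids,
# date corruption) plus the ground truth needed to validate every pipeline
# stage without a multi-gigabyte download.

#' Simulation configuration
#'
#' Defaults describe a mid-sized spontaneous-reporting snapshot: heavy-tailed
#' (Zipf, exponent 1.5) drug and event popularity, a target drug appearing as
#' primary suspect on 5 percent of reports, a truncated-geometric number of
#' reaction terms per report (mean 2.5), 5 percent duplicated caseids, onset
#' intervals log-normal with median 44 days and sdlog 1.17 (interquartile
#' ratio about 4.85, i.e. an IQR like 20-97 days), and partial/missing event
#' dates at 5 and 15 percent.
#'
#' @param n_reports number of distinct cases.
#' @param n_drugs,n_events vocabulary sizes.
#' @param drug_zipf_s,event_zipf_s Zipf exponents of the popularity marginals.
#' @param target_drug_share probability a report has the target drug as
#'   primary suspect.
#' @param implanted_signals list of `list(event = index, rho = relative
#'   risk)`: for target-drug reports the sampling odds of these events are
#'   multiplied by `rho` (odds multiplication keeps the distribution proper
#'   for any `rho >= 0`).
#' @param events_per_report_mean mean of the truncated-geometric count of
#'   reaction draws per report (at least 1).
#' @param max_events_per_report truncation cap.
#' @param duplicate_rate fraction of caseids emitted twice (the later
#'   FDA receipt date, fresh primaryid version is the intended survivor).
#' @param partial_date_rate probability the event date is truncated to 6
#'   digits.
#' @param missing_event_dt_rate probability the event date is blank.
#' @param sex_probs probabilities for F, M, missing.
#' @param age_mean,age_sd adult age distribution (years); `age_missing_rate`
#'   blanks the age; `age_child_rate` draws a pediatric age instead.
#' @param outcome_probs per-code independent probabilities of an outcome row.
#' @param tto_median_days,tto_sdlog log-normal onset-interval parameters
#'   (days), applied before date corruption.
#' @param start_base earliest therapy start date, `YYYYMMDD`.
#' @param study_days calendar span of therapy starts.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_reports = 5000L, n_drugs = 200L, n_events = 100L,
                       drug_zipf_s = 1.5, event_zipf_s = 1.5,
                       target_drug_share = 0.05, implanted_signals = list(),
                       events_per_report_mean = 2.5,
                       max_events_per_report = 10L,
                       duplicate_rate = 0.05, partial_date_rate = 0.05,
                       missing_event_dt_rate = 0.15,
                       sex_probs = c(F = 0.42, M = 0.56, U = 0.02),
                       age_mean = 62, age_sd = 12, age_missing_rate = 0.2,
                       age_child_rate = 0.002,
                       outcome_probs = c(DE = 0.25, HO = 0.22, OT = 0.12,
                                         LT = 0.01, DS = 0.005),
                       tto_median_days = 44, tto_sdlog = 1.17,
                       start_base = "20190101", study_days = 1500L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (is.data.frame(implanted_signals)) {
    cfg$implanted_signals <- lapply(seq_len(nrow(implanted_signals)), function(i)
      list(event = implanted_signals$event[i], rho = implanted_signals$rho[i]))
  }
  stopifnot(n_reports >= 1, n_drugs >= 1, n_events >= 1,
            target_drug_share >= 0, target_drug_share <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            partial_date_rate >= 0, partial_date_rate <= 1,
            missing_event_dt_rate >= 0, missing_event_dt_rate <= 1,
            events_per_report_mean >= 1, tto_median_days > 0, tto_sdlog > 0)
  for (sig in cfg$implanted_signals) {
    if (!is.numeric(sig$event) || sig$event < 1 || sig$event > n_events) {
      fs_error(sprintf("implanted event index %s outside vocabulary 1..%d",
                       format(sig$event), n_events), "sim_config_error")
    }
    if (!is.numeric(sig$rho) || sig$rho < 0) {
      fs_error("implanted rho must be a non-negative number", "sim_config_error")
    }
  }
  structure(cfg, class = "sim_config")
}

zipf_probs <- function(n, s) {
  p <- seq_len(n)^(-s)
  p / sum(p)
}

.TARGET_ALIASES <- c("LONSURF", "TRIFLURIDINE/TIPIRACIL", "TAS102",
                     "LONSURF 20MG TABLET", "FTD/TPI")

#' Target search terms used by the synthetic generator
#'
#' The generic name, abbreviations and trade name that identify the target
#' drug in synthetic drug-name strings.
#' @return character vector of match terms.
#' @export
synthetic_drug_terms <- function() {
  c("TRIFLURIDINE/TIPIRACIL", "TAS102", "FTD/TPI", "LONSURF")
}

#' PT to SOC mapping for the synthetic vocabulary
#'
#' Synthetic preferred terms `PT_001 ...` are grouped into system organ
#' classes `SOC_01 ...` in blocks of `per_soc`.
#'
#' @param n_events vocabulary size.
#' @param per_soc preferred terms per system organ class.
#' @return data.table with columns `pt`, `soc` (feed to [as_pt_soc_map()] or
#'   write as the mapping CSV).
#' @export
synthetic_pt_soc_table <- function(n_events, per_soc = 10L) {
  i <- seq_len(n_events)
  data.table::data.table(pt = sprintf("PT_%03d", i),
                         soc = sprintf("SOC_%02d", ceiling(i / per_soc)))
}

#' Generate a synthetic FAERS file set
#'
#' Produces the seven FAERS tables as in-memory data.tables (write them with
#' [write_faers_tables()]) together with the ground truth: intended
#' deduplication survivors, implanted (event, rho) pairs, per-report stratum
#' labels and uncorrupted onset days. Event sampling draws from the Zipf
#' marginal for background reports; for target-drug reports the odds of
#' implanted events are multiplied by their `rho`. Onset dates are drawn so
#' the true interval is log-normal, then corrupted by partial/missing-date
#' noise after the truth is captured. Duplicated caseids get a second version
#' with a later receipt date and fresh primaryid, which is the intended
#' dedup survivor. Byte-identical output for identical seeds.
#'
#' @param config a [sim_config()].
#' @return list with `tables` (named list of the seven tables) and `truth`
#'   (list: `survivors`, `implanted`, `report_meta`, `config`).
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_reports
  cid <- seq_len(n)
  pid <- cid * 100L + 1L
  base <- as.Date(config$start_base, format = "%Y%m%d")

  is_target <- stats::runif(n) < config$target_drug_share

  # therapy start, true onset, event date, receipt date -----------------------
  start_d <- base + sample.int(config$study_days, n, replace = TRUE) - 1L
  true_days <- as.integer(round(stats::rlnorm(n, log(config$tto_median_days),
                                              config$tto_sdlog)))
  event_d <- start_d + true_days
  fda_d <- event_d + sample.int(60L, n, replace = TRUE)

  event_s <- format_faers_date(event_d)
  corrupt <- stats::runif(n)
  event_s[corrupt < config$partial_date_rate] <-
    substr(event_s[corrupt < config$partial_date_rate], 1, 6)
  miss <- corrupt >= config$partial_date_rate &
    corrupt < config$partial_date_rate + config$missing_event_dt_rate
  event_s[miss] <- ""

  # demographics ---------------------------------------------------------------
  sexv <- sample(c("F", "M", ""), n, replace = TRUE, prob = config$sex_probs)
  child <- stats::runif(n) < config$age_child_rate
  agev <- ifelse(child, round(stats::runif(n, 2, 17)),
                 pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)),
                           18), 95))
  age_s <- as.character(agev)
  age_cod_s <- rep("YR", n)
  age_na <- stats::runif(n) < config$age_missing_rate
  age_s[age_na] <- ""
  age_cod_s[age_na] <- ""
  occp <- sample(c("CN", "MD", "PH", "OT", "HP"), n, replace = TRUE,
                 prob = c(0.42, 0.14, 0.19, 0.19, 0.06))
  ctry <- sample(c("US", "CA", "JP", "FR", "DK"), n, replace = TRUE,
                 prob = c(0.82, 0.07, 0.05, 0.03, 0.03))

  demo <- data.table::data.table(
    primaryid = as.character(pid), caseid = as.character(cid),
    fda_dt = format_faers_date(fda_d), event_dt = event_s,
    sex = sexv, age = age_s, age_cod = age_cod_s,
    occp_cod = occp, occr_country = ctry)

  # drugs ----------------------------------------------------------------------
  pdrug <- zipf_probs(config$n_drugs, config$drug_zipf_s)
  ps_idx <- sample.int(config$n_drugs, n, replace = TRUE, prob = pdrug)
  ps_name <- ifelse(is_target,
                    sample(.TARGET_ALIASES, n, replace = TRUE),
                    sprintf("DRUG_%03d", ps_idx))
  n_extra <- stats::rpois(n, 0.6)
  n_extra <- pmin(n_extra, 3L)
  extra_pid <- rep(pid, n_extra)
  extra_cid <- rep(cid, n_extra)
  extra_seq <- sequence(n_extra) + 1L
  extra_name <- sprintf("DRUG_%03d",
                        sample.int(config$n_drugs, length(extra_pid),
                                   replace = TRUE, prob = pdrug))
  extra_role <- sample(c("C", "SS", "I"), length(extra_pid), replace = TRUE,
                       prob = c(0.7, 0.2, 0.1))
  drug <- data.table::rbindlist(list(
    data.table::data.table(primaryid = as.character(pid),
                           caseid = as.character(cid),
                           drug_seq = "1", role_cod = "PS", drugname = ps_name),
    data.table::data.table(primaryid = as.character(extra_pid),
                           caseid = as.character(extra_cid),
                           drug_seq = as.character(extra_seq),
                           role_cod = extra_role, drugname = extra_name)))
  data.table::setorderv(drug, c("primaryid", "drug_seq"))

  # reactions ------------------------------------------------------------------
  pe <- zipf_probs(config$n_events, config$event_zipf_s)
  w_t <- pe
  for (sig in config$implanted_signals) w_t[sig$event] <- w_t[sig$event] * sig$rho
  w_t <- w_t / sum(w_t)
  k <- pmin(1L + stats::rgeom(n, prob = 1 / config$events_per_report_mean),
            config$max_events_per_report)
  rep_pid <- rep(pid, k)
  rep_cid <- rep(cid, k)
  rep_tgt <- rep(is_target, k)
  ev <- integer(length(rep_pid))
  if (any(!rep_tgt)) {
    ev[!rep_tgt] <- sample.int(config$n_events, sum(!rep_tgt), replace = TRUE,
                               prob = pe)
  }
  if (any(rep_tgt)) {
    ev[rep_tgt] <- sample.int(config$n_events, sum(rep_tgt), replace = TRUE,
                              prob = w_t)
  }
  reac <- data.table::data.table(primaryid = as.character(rep_pid),
                                 caseid = as.character(rep_cid),
                                 pt = sprintf("PT_%03d", ev))

  # outcomes -------------------------------------------------------------------
  outc_list <- lapply(names(config$outcome_probs), function(code) {
    hit <- stats::runif(n) < config$outcome_probs[[code]]
    data.table::data.table(primaryid = as.character(pid[hit]),
                           caseid = as.character(cid[hit]),
                           outc_cod = code)
  })
  outc <- data.table::rbindlist(outc_list)
  data.table::setorderv(outc, c("primaryid", "outc_cod"))

  # therapy dates (primary suspect drug only) ----------------------------------
  ther <- data.table::data.table(
    primaryid = as.character(pid), caseid = as.character(cid),
    dsg_drug_seq = "1", start_dt = format_faers_date(start_d), end_dt = "")

  # indications ----------------------------------------------------------------
  indi_term <- ifelse(
    is_target,
    sample(c("COLON CANCER", "RECTAL CANCER", "COLORECTAL CANCER METASTATIC",
             "PRODUCT USED FOR UNKNOWN INDICATION"), n, replace = TRUE,
           prob = c(0.45, 0.2, 0.2, 0.15)),
    sample(c("HYPERTENSION", "DIABETES MELLITUS", "DEPRESSION",
             "PRODUCT USED FOR UNKNOWN INDICATION"), n, replace = TRUE,
           prob = c(0.3, 0.25, 0.15, 0.3)))
  indi <- data.table::data.table(primaryid = as.character(pid),
                                 caseid = as.character(cid),
                                 indi_drug_seq = "1", indi_pt = indi_term)

  rpsr <- data.table::data.table(primaryid = as.character(pid),
                                 caseid = as.character(cid),
                                 rpsr_cod = sample(c("FGN", "HP", "CSM"), n,
                                                   replace = TRUE,
                                                   prob = c(0.25, 0.35, 0.4)))

  # duplicates: a later receipt-date version with a fresh primaryid ------------
  ndup <- floor(config$duplicate_rate * n)
  dup_cid <- if (ndup > 0) sort(sample(cid, ndup)) else integer(0)
  survivors <- as.character(pid)
  if (ndup > 0) {
    dup_old_pid <- as.character(dup_cid * 100L + 1L)
    dup_new_pid <- as.character(dup_cid * 100L + 2L)
    dup_demo <- demo[match(dup_old_pid, demo$primaryid)]
    dup_demo[, primaryid := dup_new_pid]
    dup_demo[, fda_dt := format_faers_date(
      parse_faers_date(fda_dt) + sample.int(90L, .N, replace = TRUE))]
    demo <- data.table::rbindlist(list(demo, dup_demo))
    clone <- function(tb) {
      extra <- tb[tb$primaryid %in% dup_old_pid]
      extra[, primaryid := dup_new_pid[match(primaryid, dup_old_pid)]]
      data.table::rbindlist(list(tb, extra))
    }
    drug <- clone(drug); reac <- clone(reac); outc <- clone(outc)
    ther <- clone(ther); indi <- clone(indi); rpsr <- clone(rpsr)
    survivors[match(dup_old_pid, survivors)] <- dup_new_pid
  }
  for (tb in list(demo, drug, reac, outc, ther, indi, rpsr)) {
    data.table::setorderv(tb, intersect(c("primaryid", "drug_seq", "pt",
                                          "outc_cod"), names(tb)))
  }

  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                 RPSR = rpsr, THER = ther, INDI = indi)
  for (id in names(tables)) data.table::setattr(tables[[id]], "table_id", id)

  implanted <- data.table::rbindlist(lapply(config$implanted_signals, function(s)
    data.table::data.table(pt = sprintf("PT_%03d", s$event), rho = s$rho)))
  if (nrow(implanted) == 0L) {
    implanted <- data.table::data.table(pt = character(0), rho = numeric(0))
  }
  truth <- list(
    survivors = survivors,
    implanted = implanted,
    report_meta = data.table::data.table(
      primaryid = survivors, caseid = as.character(cid),
      is_target = is_target, sex = sexv, age_years = ifelse(age_na, NA, agev),
      true_days = true_days),
    config = config)
  list(tables = tables, truth = truth)
}

#' Hand-written 12-record FAERS fixture
#'
#' A tiny file set exercising every edge the pipeline must handle: a duplicate
#' caseid resolved by receipt date and another resolved by the primaryid
#' tie-break, a secondary-suspect-only target report, an unmapped preferred
#' term, a partial event date, an event predating therapy start, a
#' multi-outcome report, a DEC age unit, and two therapy-start rows for one
#' drug. The accompanying `truth` lists the expected survivors, cohort,
#' contingency tables and onset statuses (hand-enumerated).
#'
#' @return list with `tables`, `map_table` (PT/SOC data.table) and `truth`.
#' @export
small_fixture <- function() {
  dt <- data.table::data.table
  demo <- dt(
    primaryid = c("1001", "1002", "1011", "1012", "1021", "1031", "1041",
                  "1051", "1061", "1071", "1081", "1091"),
    caseid = c("100", "100", "101", "101", "102", "103", "104", "105", "106",
               "107", "108", "109"),
    fda_dt = c("20200101", "20200301", "20200401", "20200401", "20200105",
               "20200110", "20200115", "20200120", "20200125", "20200130",
               "20200201", "20200205"),
    event_dt = c("20200214", "20200214", "202003", "202003", "20200301",
                 "20200101", "20200401", "", "", "20200501", "20200601",
                 "20200301"),
    sex = c("F", "F", "M", "M", "F", "M", "F", "M", "F", "M", "F", ""),
    age = c("70", "70", "55", "55", "60", "40", "66", "50", "17", "72", "45",
            "7"),
    age_cod = c("YR", "YR", "YR", "YR", "YR", "YR", "YR", "YR", "YR", "YR",
                "YR", "DEC"),
    occp_cod = c("MD", "MD", "CN", "CN", "PH", "MD", "CN", "OT", "CN", "MD",
                 "PH", "HP"),
    occr_country = c("US", "US", "US", "US", "CA", "JP", "US", "US", "FR",
                     "US", "CA", "US"))
  drug <- dt(
    primaryid = c("1001", "1002", "1011", "1012", "1021", "1021", "1031",
                  "1041", "1051", "1061", "1071", "1081", "1091", "1091"),
    caseid = c("100", "100", "101", "101", "102", "102", "103", "104", "105",
               "106", "107", "108", "109", "109"),
    drug_seq = c("1", "1", "1", "1", "1", "2", "1", "1", "1", "1", "1", "1",
                 "1", "2"),
    role_cod = c("PS", "PS", "PS", "PS", "SS", "PS", "PS", "PS", "PS", "PS",
                 "PS", "PS", "PS", "C"),
    drugname = c("LONSURF", "LONSURF", "TRIFLURIDINE\\TIPIRACIL 20MG",
                 "TRIFLURIDINE\\TIPIRACIL 20MG", "LONSURF", "OXALIPLATIN",
                 "TAS102", "CAPECITABINE", "IBUPROFEN", "Lonsurf 20mg tablet",
                 "OXALIPLATIN", "BEVACIZUMAB", "FTD/TPI", "ASPIRIN"))
  reac <- dt(
    primaryid = c("1001", "1002", "1011", "1011", "1012", "1012", "1021",
                  "1031", "1041", "1041", "1051", "1061", "1061", "1061",
                  "1071", "1081", "1081", "1091", "1091"),
    caseid = c("100", "100", "101", "101", "101", "101", "102", "103", "104",
               "104", "105", "106", "106", "106", "107", "108", "108", "109",
               "109"),
    pt = c("Nausea", "Nausea", "Anaemia", "NAUSEA", "Anaemia", "NAUSEA",
           "Vomiting", "Mystery Syndrome", "Nausea", "Headache", "Headache",
           "Diarrhoea", "Nausea", "Nausea", "Anaemia", "Vomiting", "Headache",
           "Nausea", "Anaemia"))
  outc <- dt(
    primaryid = c("1001", "1001", "1002", "1002", "1011", "1012", "1021",
                  "1041", "1071"),
    caseid = c("100", "100", "100", "100", "101", "101", "102", "104", "107"),
    outc_cod = c("DE", "HO", "DE", "HO", "HO", "HO", "OT", "HO", "DE"))
  ther <- dt(
    primaryid = c("1001", "1002", "1011", "1012", "1031", "1061", "1091",
                  "1091"),
    caseid = c("100", "100", "101", "101", "103", "106", "109", "109"),
    dsg_drug_seq = c("1", "1", "1", "1", "1", "1", "1", "1"),
    start_dt = c("20200101", "20200101", "20200201", "20200201", "20200301",
                 "20200115", "20200110", "20200105"),
    end_dt = c("", "", "", "", "", "", "", ""))
  indi <- dt(
    primaryid = c("1001", "1002", "1011", "1012", "1031", "1061", "1091"),
    caseid = c("100", "100", "101", "101", "103", "106", "109"),
    indi_drug_seq = c("1", "1", "1", "1", "1", "1", "1"),
    indi_pt = c("COLON CANCER", "COLON CANCER", "RECTAL CANCER",
                "RECTAL CANCER", "COLON CANCER",
                "COLORECTAL CANCER METASTATIC", "COLON CANCER"))
  rpsr <- dt(primaryid = c("1001", "1002", "1021"),
             caseid = c("100", "100", "102"),
             rpsr_cod = c("FGN", "FGN", "HP"))
  tables <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc,
                 RPSR = rpsr, THER = ther, INDI = indi)
  for (id in names(tables)) data.table::setattr(tables[[id]], "table_id", id)

  map_table <- dt(
    pt = c("Nausea", "Vomiting", "Diarrhoea", "Anaemia", "Headache"),
    soc = c("Gastrointestinal disorders", "Gastrointestinal disorders",
            "Gastrointestinal disorders",
            "Blood and lymphatic system disorders",
            "Nervous system disorders"))

  truth <- list(
    survivors = c("1002", "1012", "1021", "1031", "1041", "1051", "1061",
                  "1071", "1081", "1091"),
    cohort_ids = c("1002", "1012", "1031", "1061", "1091"),
    contingency_pt = dt(
      term = c("Nausea", "Anaemia", "Diarrhoea", "Mystery Syndrome"),
      a = c(4L, 2L, 1L, 1L), b = c(4L, 6L, 7L, 7L),
      c = c(1L, 1L, 0L, 0L), d = c(6L, 6L, 7L, 7L)),
    tto_status = dt(
      primaryid = c("1002", "1012", "1031", "1061", "1091"),
      status = c("included", "excluded_partial_date",
                 "excluded_event_before_start", "excluded_missing",
                 "included"),
      days = c(44L, NA_integer_, NA_integer_, NA_integer_, 56L)))
  list(tables = tables, map_table = map_table, truth = truth)
}
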