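make_demo <- function(primaryid, caseid, fda_dt) {
  n <- length(primaryid)
  data.table::data.table(
    primaryid = as.character(primaryid), caseid = as.character(caseid),
    fda_dt = as.character(fda_dt), event_dt = "", sex = "M", age = "60",
    age_cod = "YR", occp_cod = "MD", occr_country = "US")
}

cases_from_demo <- function(demo) {
  reac <- data.table::data.table(primaryid = demo$primaryid,
                                 caseid = demo$caseid, pt = "Nausea")
  drug <- data.table::data.table(primaryid = demo$primaryid,
                                 caseid = demo$caseid, drug_seq = "1",
                                 role_cod = "PS", drugname = "DRUG_A")
  assemble_cases(list(DEMO = demo, DRUG = drug, REAC = reac))
}

test_that("deduplication keeps the latest receipt date, then the highest primaryid", {
  cs <- cases_from_demo(make_demo(c(1001, 1002), c(500, 500),
                                  c("20200101", "20200301")))
  out <- deduplicate(cs)
  expect_equal(out$demo$primaryid, "1002")

  cs <- cases_from_demo(make_demo(c(1001, 1002), c(500, 500),
                                  c("20200301", "20200301")))
  expect_equal(deduplicate(cs)$demo$primaryid, "1002")

  # unparseable receipt date sorts lowest
  cs <- cases_from_demo(make_demo(c(1001, 1002), c(500, 500),
                                  c("2020", "20190101")))
  expect_equal(deduplicate(cs)$demo$primaryid, "1002")
})

test_that("deduplication is idempotent and order-insensitive", {
  demo <- make_demo(c(11, 12, 21, 31, 32, 33),
                    c(1, 1, 2, 3, 3, 3),
                    c("20200101", "20200201", "20200501",
                      "20210101", "20210101", "20200601"))
  cs <- cases_from_demo(demo)
  once <- deduplicate(cs)
  twice <- deduplicate(once)
  expect_identical(once$demo, twice$demo)
  expect_equal(once$demo$primaryid, c("12", "21", "32"))
  for (seed in 1:5) {
    set.seed(seed)
    perm <- cases_from_demo(demo[sample(.N)])
    expect_identical(deduplicate(perm)$demo, once$demo)
  }
  st <- attr(once, "dedup_stats")
  expect_equal(st$reports_in - st$removed, st$survivors)
})

test_that("target-drug matching is normalized substring matching", {
  terms <- c("TRIFLURIDINE/TIPIRACIL", "TAS102", "FTD/TPI", "LONSURF")
  expect_true(match_target_drug("LONSURF", terms))
  expect_true(match_target_drug("lonsurf 20mg tablet", terms))
  expect_true(match_target_drug("TRIFLURIDINE\\TIPIRACIL", terms))
  expect_false(match_target_drug("CAPECITABINE", terms))
  expect_equal(match_target_drug(c("LONSURF", "ASPIRIN"), terms),
               c(TRUE, FALSE))
})

test_that("cohort extraction partitions the database by role-filtered drug match", {
  fx <- small_fixture()
  cases <- deduplicate(assemble_cases(fx$tables))
  co <- extract_cohort(cases, synthetic_drug_terms())
  expect_setequal(co$cohort_ids, fx$truth$cohort_ids)
  # SS-role target report stays in the background under the PS filter
  expect_true("1021" %in% co$background_ids)
  expect_equal(sort(c(co$cohort_ids, co$background_ids)),
               sort(cases$demo$primaryid))
  # but is picked up when SS is allowed
  co2 <- extract_cohort(cases, synthetic_drug_terms(), roles = c("PS", "SS"))
  expect_true("1021" %in% co2$cohort_ids)
  expect_error(extract_cohort(cases, character(0)), class = "faers_usage_error")
})

test_that("event coding uses set semantics per report and tallies unmapped PTs", {
  fx <- small_fixture()
  cases <- deduplicate(assemble_cases(fx$tables))
  ev <- code_events(cases, as_pt_soc_map(fx$map_table))
  # report 1061 lists Nausea twice -> one pair
  expect_equal(sum(ev$primaryid == "1061" & ev$pt == "Nausea"), 1L)
  expect_equal(nrow(ev), 15L)
  un <- attr(ev, "unmapped")
  expect_equal(un$pt, "Mystery Syndrome")
  expect_equal(ev[ev$pt == "Mystery Syndrome"]$soc, "UNMAPPED")
  # SOC partition: per-SOC row counts sum to the total
  expect_equal(sum(table(ev$soc)), nrow(ev))
})

test_that("descriptive summary reproduces printed-style percentages half-up", {
  fx <- small_fixture()
  cases <- deduplicate(assemble_cases(fx$tables))
  co <- extract_cohort(cases, synthetic_drug_terms())
  t1 <- descriptive_summary(cases, co$cohort_ids)
  expect_equal(attr(t1, "n_total"), 5L)
  t1 <- data.table::as.data.table(t1)
  # cohort 1002,1012,1031,1061,1091: sexes F,M,M,F,missing
  sex <- t1[section == "Sex"]
  expect_equal(sex[level == "Female", n], 2L)
  expect_equal(sex[level == "Female", pct], 40)
  expect_equal(sum(sex$pct), 100)
  # ages 70, 55, 40, 17, 70 (7 DEC)
  age <- t1[section == "Age"]
  expect_equal(age[level == "<18", n], 1L)
  expect_equal(age[level == ">=65", n], 2L)
  # outcomes: 1002 has DE+HO (multi-outcome counts once per category),
  # 1012 HO; 1031/1061/1091 have none
  out <- t1[section == "Outcome"]
  expect_equal(out[level == "Death", n], 1L)
  expect_equal(out[level == "Hospitalization - Initial or Prolonged", n], 2L)
  expect_equal(out[level == "Missing", n], 3L)
  expect_equal(out[level == "Death", pct], 20)
})

test_that("a single-report cohort reports 100.00 percent outcomes", {
  demo <- make_demo(1, 1, "20200101")
  drug <- data.table::data.table(primaryid = "1", caseid = "1", drug_seq = "1",
                                 role_cod = "PS", drugname = "DRUG_A")
  reac <- data.table::data.table(primaryid = "1", caseid = "1", pt = "Nausea")
  outc <- data.table::data.table(primaryid = "1", caseid = "1", outc_cod = "HO")
  cs <- assemble_cases(list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc))
  t1 <- data.table::as.data.table(descriptive_summary(cs))
  expect_equal(t1[section == "Outcome" &
                    level == "Hospitalization - Initial or Prolonged", pct], 100)
})

test_that("half-up rounding reproduces the printed proportions it is defined for", {
  expect_equal(round_half_up(100 * 3501 / 8331), 42.02)
  expect_equal(round_half_up(100 * 1814 / 8331), 21.77)
  expect_equal(round_half_up(0.425 * 100, 1), 42.5)
  expect_equal(round_half_up(-0.425 * 100, 1), -42.5)
  expect_equal(round_half_up(2.675, 2), 2.68) # banker's rounding would give 2.67
})
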