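test_that("strata partition the cohort, with a missing-stratum bucket", {
  g <- generate_faers(sim_config(n_reports = 3000, target_drug_share = 0.2,
                                 seed = 5))
  cases <- deduplicate(assemble_cases(g$tables))
  co <- extract_cohort(cases, synthetic_drug_terms())
  for (strat in c("sex", "age_bin")) {
    st <- report_strata(cases, strat)
    coh <- st[st$primaryid %in% co$cohort_ids]
    expect_equal(nrow(coh), length(co$cohort_ids))
    expect_equal(sum(table(coh$stratum)), length(co$cohort_ids))
  }
})

test_that("under-reported strata are excluded with a notice, not screened", {
  fx <- small_fixture()
  cases <- deduplicate(assemble_cases(fx$tables))
  co <- extract_cohort(cases, synthetic_drug_terms())
  # the fixture has one <18 cohort report; floor 10 excludes every stratum
  # except none -> check the notice machinery on the <18 stratum specifically
  sg <- subgroup_screen(cases, co$cohort_ids, "age_bin",
                        map = as_pt_soc_map(fx$map_table), min_cohort = 2L)
  expect_true("<18" %in% sg$excluded$stratum)
  expect_match(sg$excluded[sg$excluded$stratum == "<18"]$reason, "floor")
  expect_false("<18" %in% names(sg$screens))
  expect_error(subgroup_screen(cases, co$cohort_ids, "country"))
})

test_that("a stratum-specific implanted signal is found only in its stratum", {
  # implant event 30 with rho 12 but only among reports aged >= 65:
  # build by generating two databases and relabelling ids before merging
  hits_old <- 0L; hits_young <- 0L
  n_seeds <- 5L
  for (s in seq_len(n_seeds)) {
    g_old <- generate_faers(sim_config(
      n_reports = 8000, target_drug_share = 0.12, duplicate_rate = 0,
      age_mean = 75, age_sd = 4, age_missing_rate = 0, age_child_rate = 0,
      implanted_signals = list(list(event = 30, rho = 12)), seed = 400 + s))
    g_young <- generate_faers(sim_config(
      n_reports = 8000, target_drug_share = 0.12, duplicate_rate = 0,
      age_mean = 50, age_sd = 4, age_missing_rate = 0, age_child_rate = 0,
      seed = 500 + s))
    tabs <- list()
    for (id in names(g_old$tables)) {
      young <- data.table::copy(g_young$tables[[id]])
      young[, primaryid := paste0("9", primaryid)]
      young[, caseid := paste0("9", caseid)]
      tabs[[id]] <- rbind(g_old$tables[[id]], young)
      data.table::setattr(tabs[[id]], "table_id", id)
    }
    cases <- deduplicate(assemble_cases(tabs))
    co <- extract_cohort(cases, synthetic_drug_terms())
    sg <- subgroup_screen(cases, co$cohort_ids, "age_bin",
                          map = as_pt_soc_map(synthetic_pt_soc_table(100)))
    old_sc <- data.table::as.data.table(sg$screens[[">=65"]])
    young_sc <- data.table::as.data.table(sg$screens[["18-<65"]])
    hits_old <- hits_old + isTRUE(old_sc[term == "PT_030"]$retained)
    hits_young <- hits_young + isTRUE(young_sc[term == "PT_030"]$retained)
  }
  expect_gte(hits_old, n_seeds - 1L)
  expect_lte(hits_young, 1L)
})

test_that("subgrouping with the stratifier collapsed equals the overall screen", {
  g <- generate_faers(recovery_config(seed = 88))
  cases <- deduplicate(assemble_cases(g$tables))
  co <- extract_cohort(cases, synthetic_drug_terms())
  map <- as_pt_soc_map(synthetic_pt_soc_table(100))
  ev <- code_events(cases, map)
  overall <- screen_signals(ev, co$cohort_ids, "PT")
  # force every report into one stratum by ignoring sex: union of strata
  cases_one <- cases
  cases_one$demo <- data.table::copy(cases$demo)[, sex := "F"]
  sg <- subgroup_screen(cases_one, co$cohort_ids, "sex", map = map)
  expect_equal(names(sg$screens), "F")
  expect_equal(as.data.frame(sg$screens[["F"]]), as.data.frame(overall))
})
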