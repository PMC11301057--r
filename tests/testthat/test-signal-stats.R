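test_that("contingency tables count unique report-term pairs over the full database", {
  # 3 cohort reports with PTs {X},{X,Y},{Y}; 5 background: {X},{Y},{Y},{Z},{Z}
  ev <- data.table::data.table(
    primaryid = c("c1", "c2", "c2", "c3", "b1", "b2", "b3", "b4", "b5"),
    pt = c("X", "X", "Y", "Y", "X", "Y", "Y", "Z", "Z"),
    soc = "S1")
  # hand enumeration: 4 cohort pairs (c1-X, c2-X, c2-Y, c3-Y) + 5 background
  # pairs (b1-X, b2-Y, b3-Y, b4-Z, b5-Z) = 9; for X: a=2, b=2, c=1, d=4
  tab <- build_contingency(ev, cohort_ids = c("c1", "c2", "c3"), level = "PT")
  x <- as.data.frame(tab[tab$term == "X", c("a", "b", "c", "d")])
  expect_equal(unlist(x), c(a = 2, b = 2, c = 1, d = 4))
  # a+b constant across terms; N constant; only Z (a = 0) is absent
  expect_equal(unique(tab$a + tab$b), 4)
  expect_equal(unique(tab$N), 9)
  expect_setequal(tab$term, c("X", "Y"))
  # terms with a cohort case partition the pairs once a=0 terms are added back
  expect_equal(sum(tab$a + tab$c) + 2L, unique(tab$N))
})

test_that("ROR, PRR and chi-squared match independent oracles to 1e-9", {
  expect_equal(ror_stat(10, 90, 100, 9900)$ror, 11)
  expect_equal(prr_stat(10, 90, 100, 9900)$prr, 10)

  suite <- random_2x2_suite(50, seed = 101)
  got_r <- ror_stat(suite$a, suite$b, suite$c, suite$d)
  got_p <- prr_stat(suite$a, suite$b, suite$c, suite$d)
  want_r <- ror_oracle(suite$a, suite$b, suite$c, suite$d)
  expect_equal(got_r$ror, want_r$ror, tolerance = 1e-9)
  expect_equal(got_r$ror_low, want_r$low, tolerance = 1e-9)
  expect_equal(got_r$ror_high, want_r$high, tolerance = 1e-9)
  expect_equal(got_p$prr, prr_oracle(suite$a, suite$b, suite$c, suite$d),
               tolerance = 1e-9)
  for (i in seq_len(nrow(suite))) {
    expect_equal(got_p$chi2[i],
                 chi2_oracle(suite$a[i], suite$b[i], suite$c[i], suite$d[i]),
                 tolerance = 1e-9)
    expect_equal(
      got_p$chi2[i],
      unname(suppressWarnings(chisq.test(
        matrix(c(suite$a[i], suite$b[i], suite$c[i], suite$d[i]),
               2, 2, byrow = TRUE), correct = FALSE))$statistic),
      tolerance = 1e-9)
  }
})

test_that("symmetric and independence tables give null statistics", {
  expect_equal(ror_stat(5, 5, 5, 5)$ror, 1)
  r <- ror_stat(5, 5, 5, 5)
  expect_true(r$ror_low < 1 && r$ror_high > 1)
  p <- prr_stat(10, 90, 100, 900) # ad = bc
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)
  # scaled independence table: IC near zero under the weak prior
  ic <- bcpnn_ic(100, 9900, 9900, 980100)
  expect_gt(ic$ic, -0.1)
  expect_lt(ic$ic, 0.1)
})

test_that("zero cells are non-evaluable, not errors", {
  r <- ror_stat(3, 0, 5, 100)
  expect_true(is.na(r$ror))
  p <- prr_stat(0, 0, 5, 100) # zero a+b margin
  expect_true(is.na(p$prr))
  ev <- evaluate_criteria(data.table::data.table(
    a = 3, ror_low = NA_real_, prr = NA_real_, chi2 = NA_real_,
    ic025 = 0.5, eb05 = 3))
  expect_false(ev$flag_ror)
  expect_false(ev$flag_prr)
  expect_true(ev$flag_bcpnn)
  expect_false(ev$retained)
})

test_that("the Yates switch applies the continuity correction", {
  p0 <- prr_stat(10, 90, 100, 9900)
  p1 <- prr_stat(10, 90, 100, 9900, yates = TRUE)
  expect_lt(p1$chi2, p0$chi2)
  m <- matrix(c(10, 90, 100, 9900), 2, 2, byrow = TRUE)
  expect_equal(p1$chi2,
               unname(suppressWarnings(chisq.test(m, correct = TRUE))$statistic),
               tolerance = 1e-9)
})

test_that("the BCPNN credibility bound sits strictly below the expectation", {
  suite <- random_2x2_suite(30, seed = 7)
  ic <- bcpnn_ic(suite$a, suite$b, suite$c, suite$d)
  expect_true(all(ic$ic025 < ic$ic))
})

test_that("disproportionality statistics agree in sign and grow with the observed count", {
  suite <- random_2x2_suite(40, seed = 11)
  r <- ror_stat(suite$a, suite$b, suite$c, suite$d)
  p <- prr_stat(suite$a, suite$b, suite$c, suite$d)
  s <- sign(suite$a * suite$d - suite$b * suite$c)
  expect_equal(sign(r$ror - 1), s)
  expect_equal(sign(p$prr - 1), s)

  # fixed margins: increase a, compensate d; every statistic is non-decreasing
  n1 <- 200; n2 <- 300; N <- 20000
  a <- 5:50
  b <- n1 - a; c <- n2 - a; d <- N - n1 - n2 + a
  prior <- structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                          w = 1 / 3), class = "mgps_prior")
  ror <- ror_stat(a, b, c, d)$ror
  prr <- prr_stat(a, b, c, d)$prr
  ic <- bcpnn_ic(a, b, c, d)$ic
  eb <- ebgm_stat(a, rep((n1 * n2) / N, length(a)), prior)$ebgm
  expect_true(all(diff(ror) > 0))
  expect_true(all(diff(prr) > 0))
  expect_true(all(diff(ic) > 0))
  expect_true(all(diff(eb) > 0))
})

test_that("screening returns every term with a cohort case, ranked by SOC then count", {
  g <- generate_faers(recovery_config(seed = 42))
  sc <- screen_synthetic(g)
  cases <- deduplicate(assemble_cases(g$tables))
  cohort <- extract_cohort(cases, synthetic_drug_terms())
  ev <- code_events(cases, as_pt_soc_map(synthetic_pt_soc_table(100)))
  n_terms <- length(unique(ev[ev$primaryid %in% cohort$cohort_ids]$pt))
  expect_equal(nrow(sc), n_terms)
  expect_true(all(sc$a >= 1))
  # ordering: soc ascending, then a descending within soc
  dt <- data.table::as.data.table(sc)
  expect_true(all(dt[, all(diff(a) <= 0), by = soc]$V1))
  expect_false(is.unsorted(dt$soc))
  # retained implies every individual flag
  expect_true(all(dt[retained == TRUE,
                     flag_ror & flag_prr & flag_bcpnn & flag_mgps]))
  # statistic set per term is complete
  expect_true(all(c("a", "ror", "ror_low", "ror_high", "prr", "chi2",
                    "ebgm", "eb05", "ic", "ic025") %in% names(dt)))
})

test_that("implanted elevated-risk terms are retained and null terms are not (small study)", {
  hits <- 0L; fp_seeds <- 0L
  n_seeds <- 15L
  for (s in seq_len(n_seeds)) {
    g <- generate_faers(recovery_config(seed = 9000 + s))
    sc <- data.table::as.data.table(screen_synthetic(g))
    imp <- sc[term %in% g$truth$implanted$pt]
    hits <- hits + (nrow(imp) == 3L && all(imp$retained))
    fp_seeds <- fp_seeds + any(sc[!term %in% g$truth$implanted$pt]$retained)
  }
  expect_gte(hits, n_seeds - 1L)
  expect_lte(fp_seeds, 1L)
})

test_that("the any-k retention rule is laxer than the all-four conjunction", {
  g <- generate_faers(recovery_config(seed = 314))
  sc_all <- data.table::as.data.table(screen_synthetic(g))
  sc_any <- data.table::as.data.table(
    screen_synthetic(g, criteria = signal_criteria(rule = "any", n_required = 1)))
  expect_gte(sum(sc_any$retained), sum(sc_all$retained))
  expect_true(all(sc_all[retained == TRUE]$term %in%
                    sc_any[retained == TRUE]$term))
})
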