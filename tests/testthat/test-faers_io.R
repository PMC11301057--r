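test_that("reading a FAERS table parses fields verbatim from the header order", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$event_dt$sex$age$age_cod$fda_dt$occp_cod$occr_country",
               "1001$500$20200101$M$63$YR$20200301$MD$US"), p)
  dt <- read_faers_table(p, "DEMO")
  expect_equal(nrow(dt), 1L)
  expect_equal(dt$sex, "M")
  expect_equal(dt$age, "63")
  expect_equal(dt$line_no, 2L)
  expect_identical(attr(dt, "table_id"), "DEMO")
})

test_that("field-count mismatches are dialect errors naming the line", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$event_dt$sex$age$age_cod$fda_dt$occp_cod$occr_country",
               "1001$500$20200101$M$63$YR$20200301$MD$US",
               "1002$501$20200101$F$20200301"), p)
  expect_error(read_faers_table(p, "DEMO"), "line 3", class = "faers_dialect_error")
})

test_that("a header missing schema columns is a schema error naming both sets", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$pt", "1$1$Nausea"), p)
  err <- tryCatch(read_faers_table(p, "DEMO"), condition = identity)
  expect_s3_class(err, "faers_schema_error")
  expect_match(conditionMessage(err), "header columns")
  expect_match(conditionMessage(err), "schema columns")
  expect_match(conditionMessage(err), "fda_dt")
})

test_that("write then read round-trips record sequences, preserving order and trailing blanks", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  for (id in names(fx$tables)) {
    p <- file.path(dir, paste0(id, ".txt"))
    write_faers_table(fx$tables[[id]], p)
    back <- read_faers_table(p, id)
    orig <- data.table::as.data.table(fx$tables[[id]])
    expect_equal(as.data.frame(back[, names(orig), with = FALSE]),
                 as.data.frame(orig), ignore_attr = TRUE)
    expect_true(all(diff(back$line_no) == 1L))
    # second write is byte-stable
    p2 <- file.path(dir, paste0(id, "_2.txt"))
    write_faers_table(back, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("writing an empty record set emits only the header", {
  p <- withr::local_tempfile(fileext = ".txt")
  empty <- data.table::data.table(primaryid = character(0), caseid = character(0),
                                  pt = character(0))
  write_faers_table(empty, p, table_id = "REAC")
  expect_equal(readLines(p), "primaryid$caseid$pt")
  expect_equal(nrow(read_faers_table(p, "REAC")), 0L)
})

test_that("unknown extra columns are preserved but do not break the schema", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("primaryid$caseid$pt$drug_rec_act", "1$1$Nausea$"), p)
  dt <- read_faers_table(p, "REAC")
  expect_true("drug_rec_act" %in% names(dt))
  expect_equal(dt$pt, "Nausea")
})

test_that("PT->SOC mapping is case- and whitespace-insensitive with conflict detection", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pt,soc", "Anaemia,Blood and lymphatic system disorders",
               "NAUSEA,Gastrointestinal disorders",
               "nausea ,Gastrointestinal disorders"), p)
  m <- load_pt_soc_map(p)
  expect_equal(soc_for_pt(m, "anaemia"), "Blood and lymphatic system disorders")
  expect_equal(soc_for_pt(m, "  Nausea "), "Gastrointestinal disorders")
  expect_true(is.na(soc_for_pt(m, "Unmapped PT X")))

  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pt,soc", "Nausea,Gastrointestinal disorders",
               "NAUSEA,Nervous system disorders"), p2)
  expect_error(load_pt_soc_map(p2), "NAUSEA", class = "ptsoc_conflict_error")
})
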