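# standard fixture pipeline run shared by the pipeline and acceptance tests
# (subgroup floor of 2 so the tiny fixture still exercises the subgroup stage;
# the <18 stratum, with one report, stays below the floor and is excluded)
run_fixture_pipeline <- function(out_dir) {
  fx <- small_fixture()
  in_dir <- file.path(tempfile("fixture_in_"))
  write_faers_tables(fx$tables, in_dir)
  map_path <- tempfile("map_", fileext = ".csv")
  data.table::fwrite(fx$map_table, map_path)
  cfg <- faers_run_config(input_dir = in_dir, pt_soc_map = map_path,
                          drug_terms = synthetic_drug_terms(),
                          out_dir = out_dir, min_cohort = 2L)
  suppressWarnings(faers_run(cfg)) # tiny fixture: MGPS cell-count warning
}

golden_dir <- function() {
  system.file("extdata", "golden", package = "faersignal")
}
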