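# End-to-end orchestration: ingest -> dedup -> cohort -> screen -> subgroup /
# time-to-onset -> report bundle, with a run manifest accounting for every
# report at every stage.

#' Pipeline run configuration
#'
#' @param input_dir directory holding the seven "$"-delimited FAERS tables.
#' @param pt_soc_map path to the PT/SOC mapping file, or an object accepted by
#'   [as_pt_soc_map()].
#' @param drug_terms target search terms.
#' @param out_dir output directory for the CSV/JSON bundle.
#' @param roles cohort role filter (default primary suspect).
#' @param criteria a [signal_criteria()] object.
#' @param age_cuts age-bin cut points.
#' @param min_cohort subgroup cohort floor, see [subgroup_screen()].
#' @param top_k subgroup comparison depth.
#' @param tto_breaks onset bin edges, see [summarize_tto()].
#' @param top_indications,top_countries Table-1 list depths.
#' @return a `faers_run_config` list.
#' @export
faers_run_config <- function(input_dir, pt_soc_map, drug_terms, out_dir,
                             roles = "PS", criteria = signal_criteria(),
                             age_cuts = c(18, 65), min_cohort = 10L,
                             top_k = 15L, tto_breaks = c(30, 60, 90, 180, 365),
                             top_indications = 7L, top_countries = 5L) {
  structure(as.list(environment()), class = "faers_run_config")
}

round_stat_cols <- function(x, digits = 4) {
  x <- data.table::copy(data.table::as.data.table(x))
  for (j in names(x)) {
    if (is.double(x[[j]])) data.table::set(x, j = j, value = round(x[[j]], digits))
  }
  x
}

screen_csv_cols <- function(sc) {
  keep <- intersect(c("term", "soc", "a", "b", "c", "d", "N", "E", "ror",
                      "ror_low", "ror_high", "prr", "chi2", "ic", "ic025",
                      "ebgm", "eb05", "flag_ror", "flag_prr", "flag_bcpnn",
                      "flag_mgps", "retained"), names(sc))
  round_stat_cols(data.table::as.data.table(sc)[, ..keep])
}

#' Run the full signal-mining pipeline
#'
#' Fixed stage order: read tables, assemble cases, deduplicate, extract the
#' target-drug cohort, code events, descriptive summary, PT- and SOC-level
#' screens, sex and age subgroup screens, time-to-onset analysis, then write
#' the output bundle (CSV tables plus a JSON manifest in which every exclusion
#' is counted). Analysis stages are deterministic: identical configuration and
#' inputs give identical outputs. Any stage error aborts with the stage name,
#' after writing the manifest recorded so far.
#'
#' @param config a [faers_run_config()], a list with its fields, or the path
#'   to a YAML file of them.
#' @return (invisibly) a `faers_run` list with the in-memory results
#'   (`cases`, `cohort`, `table1`, `screen_pt`, `screen_soc`, `subgroup_sex`,
#'   `subgroup_age`, `tto`, `tto_summary`, `manifest`, `files`).
#' @export
faers_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "faers_run_config")) {
    config <- do.call(faers_run_config, config)
  }
  cfg <- config
  if (!inherits(cfg$criteria, "signal_criteria")) {
    cfg$criteria <- do.call(signal_criteria, as.list(cfg$criteria))
  }

  # startup validation: fail before any output is produced
  if (!dir.exists(cfg$input_dir)) {
    fs_error(sprintf("pipeline stage 'startup' failed: input_dir does not exist: %s",
                     cfg$input_dir), "pipeline_stage_error")
  }
  if (is.character(cfg$pt_soc_map) && !file.exists(cfg$pt_soc_map)) {
    fs_error(sprintf("pipeline stage 'startup' failed: pt_soc_map does not exist: %s",
                     cfg$pt_soc_map), "pipeline_stage_error")
  }
  if (length(cfg$drug_terms) == 0L) {
    fs_error("pipeline stage 'startup' failed: drug_terms is empty",
             "pipeline_stage_error")
  }

  manifest <- list(
    package = "faersignal",
    version = as.character(utils::packageVersion("faersignal")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(input_dir = cfg$input_dir,
                  drug_terms = cfg$drug_terms, roles = cfg$roles,
                  criteria = unclass(cfg$criteria),
                  age_cuts = cfg$age_cuts, min_cohort = cfg$min_cohort,
                  tto_breaks = cfg$tto_breaks))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      try(jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                               auto_unbox = TRUE, pretty = TRUE, digits = NA),
          silent = TRUE)
      fs_error(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "pipeline_stage_error")
    })
  }

  map <- stage("load_map", {
    if (is.character(cfg$pt_soc_map)) load_pt_soc_map(cfg$pt_soc_map)
    else if (inherits(cfg$pt_soc_map, "pt_soc_map")) cfg$pt_soc_map
    else as_pt_soc_map(cfg$pt_soc_map)
  })

  tables <- stage("ingest", read_faers_tables(cfg$input_dir))
  cases_raw <- stage("assemble", assemble_cases(tables))
  manifest$counts <- list(reports_read = nrow(cases_raw$demo))

  cases <- stage("deduplicate", deduplicate(cases_raw))
  ds <- attr(cases, "dedup_stats")
  manifest$counts$duplicates_removed <- ds$removed
  manifest$counts$deduplicated_reports <- ds$survivors

  cohort <- stage("cohort", extract_cohort(cases, cfg$drug_terms, cfg$roles))
  manifest$counts$cohort_reports <- length(cohort$cohort_ids)
  manifest$counts$background_reports <- length(cohort$background_ids)

  ev <- stage("code_events", code_events(cases, map))
  manifest$counts$pt_pairs <- nrow(ev)
  manifest$counts$unmapped_pts <- nrow(attr(ev, "unmapped"))

  tab1 <- stage("table1", descriptive_summary(
    cases, cohort$cohort_ids, age_cuts = cfg$age_cuts,
    top_indications = cfg$top_indications, top_countries = cfg$top_countries))

  screen_pt <- stage("screen_pt",
                     screen_signals(ev, cohort$cohort_ids, "PT", cfg$criteria))
  screen_soc <- stage("screen_soc",
                      screen_signals(ev, cohort$cohort_ids, "SOC", cfg$criteria))
  manifest$counts$pt_terms <- nrow(screen_pt)
  manifest$counts$soc_terms <- nrow(screen_soc)
  manifest$counts$retained_pt <- sum(screen_pt$retained %||% logical(0))
  manifest$counts$retained_soc <- sum(screen_soc$retained %||% logical(0))

  sub_sex <- stage("subgroup_sex", subgroup_screen(
    cases, cohort$cohort_ids, "sex", map = map, criteria = cfg$criteria,
    min_cohort = cfg$min_cohort, top_k = cfg$top_k, age_cuts = cfg$age_cuts))
  sub_age <- stage("subgroup_age", subgroup_screen(
    cases, cohort$cohort_ids, "age_bin", map = map, criteria = cfg$criteria,
    min_cohort = cfg$min_cohort, top_k = cfg$top_k, age_cuts = cfg$age_cuts))

  tto <- stage("tto", tto_records(cases, cohort$cohort_ids, cfg$drug_terms,
                                  cfg$roles))
  ttos <- stage("tto_summary", summarize_tto(tto, breaks = cfg$tto_breaks))
  manifest$counts$tto <- c(list(included = ttos$n_included),
                           as.list(ttos$excluded))
  manifest$tto_summary <- list(median = ttos$median, q1 = ttos$q1,
                               q3 = ttos$q3)

  files <- stage("write_bundle", {
    out <- character(0)
    wr <- function(x, name) {
      p <- file.path(cfg$out_dir, name)
      data.table::fwrite(x, p)
      out <<- c(out, p)
    }
    wr(data.table::as.data.table(tab1), "table1.csv")
    wr(screen_csv_cols(screen_pt), "signals_pt.csv")
    wr(screen_csv_cols(screen_soc), "signals_soc.csv")
    for (nm in c("sex", "age")) {
      sg <- if (nm == "sex") sub_sex else sub_age
      parts <- lapply(names(sg$screens), function(v) {
        cbind(data.table::data.table(stratum = v), screen_csv_cols(sg$screens[[v]]))
      })
      if (length(parts)) {
        wr(data.table::rbindlist(parts), sprintf("subgroup_%s.csv", nm))
      }
      if (nrow(sg$top)) {
        wr(round_stat_cols(sg$top), sprintf("subgroup_%s_top.csv", nm))
      }
      if (nrow(sg$excluded)) {
        manifest$subgroup_exclusions[[nm]] <- sg$excluded
      }
    }
    wr(tto, "tto_records.csv")
    wr(ttos$bins, "tto_summary.csv")
    out
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  files <- c(files, file.path(cfg$out_dir, "manifest.json"))

  invisible(structure(list(
    cases = cases, cohort = cohort, table1 = tab1, events = ev,
    screen_pt = screen_pt, screen_soc = screen_soc,
    subgroup_sex = sub_sex, subgroup_age = sub_age,
    tto = tto, tto_summary = ttos, manifest = manifest, files = files),
    class = "faers_run"))
}
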