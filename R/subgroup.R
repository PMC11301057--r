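# Demographic subgroup re-screening: restrict the whole database (cohort and
# background) to a stratum, rebuild the tables, rerun the screen.

#' Stratum labels per report
#'
#' @param cases a `faers_cases` object.
#' @param stratifier `"sex"` or `"age_bin"`.
#' @param age_cuts cut points for the age bins.
#' @return data.table with `primaryid`, `stratum` (`"missing"` where the
#'   stratifier is absent or unparseable).
#' @export
report_strata <- function(cases, stratifier = c("sex", "age_bin"),
                          age_cuts = c(18, 65)) {
  stratifier <- match.arg(stratifier)
  d <- cases$demo
  if (stratifier == "sex") {
    s <- toupper(trimws(d$sex))
    s[!s %in% c("F", "M")] <- "missing"
  } else {
    s <- age_bin_label(age_in_years(d$age, d$age_cod), age_cuts)
  }
  data.table::data.table(primaryid = d$primaryid, stratum = s)
}

#' Subgroup signal screening
#'
#' For each stratum of the chosen demographic stratifier, restricts the entire
#' database to the stratum's reports, rebuilds the contingency tables and
#' reruns [screen_signals()]. Strata whose cohort falls below `min_cohort`
#' reports are excluded with a notice rather than screened (under-reported
#' strata, e.g. children, produce meaningless tables). A ranked top-k PT table
#' per stratum is emitted for side-by-side comparison.
#'
#' @param cases deduplicated `faers_cases` (full database).
#' @param cohort_ids primaryids of the target-drug cohort.
#' @param stratifier `"sex"` or `"age_bin"`.
#' @param level `"PT"` or `"SOC"`.
#' @param map optional `pt_soc_map` for SOC coding.
#' @param criteria a [signal_criteria()] object.
#' @param min_cohort minimum cohort reports for a stratum to be screened.
#' @param top_k rows per stratum in the comparison table.
#' @param age_cuts cut points when `stratifier = "age_bin"`.
#' @return a `subgroup_screen` list: `screens` (named list of `signal_screen`
#'   tables), `top` (ranked comparison table), `excluded` (stratum, cohort
#'   size, reason), `stratifier`.
#' @export
subgroup_screen <- function(cases, cohort_ids, stratifier = c("sex", "age_bin"),
                            level = "PT", map = NULL,
                            criteria = signal_criteria(), min_cohort = 10L,
                            top_k = 15L, age_cuts = c(18, 65)) {
  stratifier <- match.arg(stratifier)
  strata <- report_strata(cases, stratifier, age_cuts)
  ev <- code_events(cases, map)
  # fixed, locale-independent stratum order
  lev <- if (stratifier == "sex") c("F", "M", "missing")
         else c(sprintf("<%d", age_cuts[1]),
                sprintf("%d-<%d", age_cuts[1], age_cuts[2]),
                sprintf(">=%d", age_cuts[2]), "missing")
  screens <- list()
  excluded <- list()
  tops <- list()
  for (v in intersect(lev, unique(strata$stratum))) {
    ids_v <- strata[stratum == v, primaryid]
    coh_v <- intersect(cohort_ids, ids_v)
    if (length(coh_v) < min_cohort) {
      excluded[[v]] <- data.table::data.table(
        stratum = v, cohort_n = length(coh_v),
        reason = sprintf("cohort below floor of %d reports", min_cohort))
      next
    }
    sc <- screen_signals(ev[ev$primaryid %in% ids_v], coh_v, level = level,
                         criteria = criteria)
    screens[[v]] <- sc
    if (nrow(sc)) {
      tk <- data.table::as.data.table(sc)[order(-a, term)][seq_len(min(top_k, .N))]
      tk[, `:=`(stratum = v, rank_in_stratum = .I)]
      tops[[v]] <- tk[, .(stratum, rank_in_stratum, term, soc, a, ror,
                          retained)]
    }
  }
  structure(list(
    screens = screens,
    top = if (length(tops)) data.table::rbindlist(tops)
          else data.table::data.table(),
    excluded = if (length(excluded)) data.table::rbindlist(excluded)
               else data.table::data.table(stratum = character(0),
                                           cohort_n = integer(0),
                                           reason = character(0)),
    stratifier = stratifier), class = "subgroup_screen")
}

#' @export
print.subgroup_screen <- function(x, ...) {
  cat(sprintf("<subgroup_screen> by %s: %d screened stratum/strata (%s)%s\n",
              x$stratifier, length(x$screens),
              paste(names(x$screens), collapse = ", "),
              if (nrow(x$excluded))
                sprintf("; %d excluded (%s)", nrow(x$excluded),
                        paste(x$excluded$stratum, collapse = ", "))
              else ""))
  invisible(x)
}
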