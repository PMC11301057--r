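# Case assembly, deduplication, target-drug cohort extraction, event coding.

empty_member <- function(cols) {
  data.table::setDT(stats::setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols))
}

#' Assemble case reports from parsed FAERS tables
#'
#' Joins nothing and interprets nothing: it selects the schema columns from
#' each table and bundles them into one `faers_cases` object keyed by
#' `primaryid`, the unit all later stages filter on.
#'
#' @param tables named list of parsed FAERS tables (names are table ids);
#'   DEMO, DRUG and REAC are required, the rest default to empty.
#' @return a `faers_cases` object: list of data.tables `demo`, `drugs`,
#'   `reactions`, `outcomes`, `ther`, `indications`, `rpsr`.
#' @export
assemble_cases <- function(tables) {
  names(tables) <- toupper(names(tables))
  for (id in c("DEMO", "DRUG", "REAC")) {
    if (is.null(tables[[id]])) {
      fs_error(sprintf("assemble_cases needs a %s table", id),
               "faers_usage_error")
    }
  }
  take <- function(id) {
    cols <- .FAERS_SCHEMAS[[id]]
    x <- tables[[id]]
    if (is.null(x)) return(empty_member(cols))
    out <- data.table::as.data.table(x)[, cols, with = FALSE]
    for (j in cols) data.table::set(out, j = j, value = as.character(out[[j]]))
    out
  }
  obj <- list(
    demo = take("DEMO"),
    drugs = take("DRUG"),
    reactions = take("REAC"),
    outcomes = take("OUTC"),
    ther = take("THER"),
    indications = take("INDI"),
    rpsr = take("RPSR")
  )
  structure(obj, class = "faers_cases")
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d reports, %d drug rows, %d reaction rows\n",
              nrow(x$demo), nrow(x$drugs), nrow(x$reactions)))
  invisible(x)
}

filter_cases <- function(cases, primaryids) {
  out <- lapply(cases, function(tb) tb[tb$primaryid %in% primaryids])
  structure(out, class = "faers_cases")
}

#' Deduplicate FAERS case reports
#'
#' FAERS cases recur across quarterly releases under one CASEID. For each
#' CASEID the report with the most recent FDA receipt date (`fda_dt`) is kept;
#' among ties on `fda_dt`, the highest PRIMARYID wins (numeric comparison when
#' both ids are digit strings, lexicographic otherwise). Unparseable receipt
#' dates sort lowest. The operation is idempotent and order-insensitive, and
#' the result is ordered by ascending caseid.
#'
#' @param cases a `faers_cases` object.
#' @return a deduplicated `faers_cases`; attribute `dedup_stats` holds
#'   `reports_in`, `survivors` and `removed` counts.
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  d <- data.table::copy(cases$demo)
  if (nrow(d) == 0L) {
    out <- filter_cases(cases, character(0))
    data.table::setattr(out, "dedup_stats",
                        list(reports_in = 0L, survivors = 0L, removed = 0L))
    return(out)
  }
  d[, .fda := ifelse(is_full_date_string(trimws(fda_dt)),
                     suppressWarnings(as.numeric(fda_dt)), -Inf)]
  d[, .pid := id_order_key(primaryid)]
  data.table::setorderv(d, c(".fda", ".pid"), order = c(-1L, -1L))
  surv <- d[, .SD[1L], by = caseid]
  surv <- surv[order(id_order_key(caseid))]
  out <- filter_cases(cases, surv$primaryid)
  out$demo <- out$demo[match(surv$primaryid, out$demo$primaryid)]
  data.table::setattr(out, "dedup_stats", list(
    reports_in = nrow(cases$demo),
    survivors = nrow(surv),
    removed = nrow(cases$demo) - nrow(surv)))
  out
}

#' Match drug name strings against target terms
#'
#' Both sides are uppercased with punctuation and whitespace runs collapsed to
#' single spaces, then matching is substring-based: FAERS `drugname` strings
#' carry dose and formulation text ("LONSURF 20MG TABLET"), so exact equality
#' would miss most target rows.
#'
#' @param drug_name character vector of FAERS drug name strings.
#' @param drug_terms character vector of target search terms (generic name,
#'   abbreviations, trade names).
#' @return logical vector, `TRUE` where any term matches.
#' @export
#' @examples
#' match_target_drug("lonsurf 20mg tablet",
#'                   c("TRIFLURIDINE/TIPIRACIL", "TAS102", "FTD/TPI", "LONSURF"))
match_target_drug <- function(drug_name, drug_terms) {
  if (length(drug_terms) == 0L) {
    fs_error("drug_terms must be non-empty", "faers_usage_error")
  }
  nm <- normalize_drug(drug_name)
  hit <- rep(FALSE, length(nm))
  for (term in normalize_drug(drug_terms)) {
    if (!nzchar(term)) next
    hit <- hit | grepl(term, nm, fixed = TRUE)
  }
  hit
}

#' Extract the target-drug cohort
#'
#' Partitions a deduplicated database into the analysis cohort (reports with
#' at least one drug matching `drug_terms` in one of the requested role codes,
#' primary suspect by default) and the background (everything else).
#'
#' @param cases deduplicated `faers_cases`.
#' @param drug_terms target search terms, see [match_target_drug()].
#' @param roles FAERS role codes defining cohort membership
#'   (default `"PS"`; codes are PS, SS, C, I).
#' @return a `faers_cohort` list: `cohort_ids`, `background_ids`,
#'   `drug_terms`, `roles`.
#' @export
extract_cohort <- function(cases, drug_terms, roles = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  if (length(drug_terms) == 0L) {
    fs_error("drug_terms must be non-empty", "faers_usage_error")
  }
  dr <- cases$drugs
  hit_ids <- unique(dr[toupper(trimws(dr$role_cod)) %in% toupper(roles) &
                         match_target_drug(dr$drugname, drug_terms),
                       primaryid])
  all_ids <- cases$demo$primaryid
  cohort_ids <- all_ids[all_ids %in% hit_ids]
  structure(list(cohort_ids = cohort_ids,
                 background_ids = setdiff(all_ids, cohort_ids),
                 drug_terms = drug_terms, roles = roles),
            class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat(sprintf("<faers_cohort> %d cohort / %d background reports (roles: %s)\n",
              length(x$cohort_ids), length(x$background_ids),
              paste(x$roles, collapse = ",")))
  invisible(x)
}

#' Code reaction terms at PT and SOC level
#'
#' One row per unique (report, preferred term) pair — a PT repeated within one
#' report counts once, which is the counting unit every disproportionality
#' statistic uses. SOC is attached through the mapping; unmapped PTs carry
#' SOC `"UNMAPPED"` and are tallied in the `unmapped` attribute rather than
#' dropped.
#'
#' @param cases a `faers_cases` object (normally the full deduplicated
#'   database: cohort and background together).
#' @param map a `pt_soc_map`, or `NULL` to leave every SOC `"UNMAPPED"`.
#' @return data.table with `primaryid`, `pt` (display form), `soc`; attribute
#'   `unmapped` is a tally (pt, n) of PTs without a mapping.
#' @export
code_events <- function(cases, map = NULL) {
  stopifnot(inherits(cases, "faers_cases"))
  r <- cases$reactions[trimws(cases$reactions$pt) != ""]
  if (nrow(r) == 0L) {
    out <- data.table::data.table(primaryid = character(0), pt = character(0),
                                  soc = character(0))
    data.table::setattr(out, "unmapped",
                        data.table::data.table(pt = character(0), n = integer(0)))
    return(out)
  }
  r <- data.table::data.table(primaryid = r$primaryid,
                              pt_key = normalize_term(r$pt),
                              pt_disp = squish(r$pt))
  disp <- r[, .(pt = pt_disp[1L]), by = pt_key] # first spelling seen, deterministic
  ev <- unique(r[, .(primaryid, pt_key)])
  ev <- disp[ev, on = "pt_key"]
  ev[, soc := if (is.null(map)) NA_character_ else soc_for_pt(map, pt_key)]
  unmapped <- ev[is.na(soc), .(n = .N), by = pt][order(-n, pt)]
  ev[is.na(soc), soc := "UNMAPPED"]
  out <- ev[, .(primaryid, pt, soc)]
  data.table::setattr(out, "unmapped", unmapped[, .(pt, n)])
  out[]
}
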