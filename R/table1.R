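# Table-1 style descriptive summary of a report cohort.

.OUTCOME_LABELS <- c(DE = "Death", LT = "Life-Threatening",
                     HO = "Hospitalization - Initial or Prolonged",
                     DS = "Disability", CA = "Congenital Anomaly",
                     RI = "Required Intervention", OT = "Other Serious")

.OCCP_LABELS <- c(CN = "Consumer", MD = "Physician", PH = "Pharmacist",
                  OT = "Other health-professional", HP = "Health Professional",
                  LW = "Lawyer", RN = "Registered Nurse")

#' Descriptive summary of a report cohort
#'
#' Counts and percentages by sex, age bin, outcome code, indication, reporter
#' occupation, reporter country and receipt year. Percentages are rounded
#' half-up to two decimals. Denominators: the cohort size for every category
#' except indications, which use the total number of indication entries (a
#' report can carry several). A report with multiple outcome codes contributes
#' to each outcome category; reports with no outcome row count as Missing.
#' Top-k lists (indications, countries) are ranked by count with ties broken
#' alphabetically.
#'
#' @param cases a deduplicated `faers_cases` object.
#' @param cohort_ids primaryids of the cohort (default: all reports in
#'   `cases`).
#' @param age_cuts two cut points for the age bins (default `c(18, 65)`:
#'   bins <18, 18-<65, >=65).
#' @param top_indications,top_countries how many top categories to list.
#' @return a `faers_table1`: data.table with `section`, `level`, `n`, `pct`;
#'   attribute `n_total` is the cohort size.
#' @export
descriptive_summary <- function(cases, cohort_ids = NULL, age_cuts = c(18, 65),
                                top_indications = 7L, top_countries = 5L) {
  stopifnot(inherits(cases, "faers_cases"))
  ids <- cohort_ids %||% cases$demo$primaryid
  n_total <- length(ids)
  demo <- cases$demo[cases$demo$primaryid %in% ids]

  count_block <- function(section, levels_vec, denom = n_total,
                          keep_order = NULL, top_k = NULL) {
    if (length(levels_vec) == 0L) {
      tb <- data.table::data.table(level = character(0), n = integer(0))
    } else {
      tb <- data.table::as.data.table(table(levels_vec))
      data.table::setnames(tb, c("level", "n"))
    }
    tb[, level := as.character(level)]
    tb[, n := as.integer(n)]
    tb <- tb[order(-n, level)]
    if (!is.null(keep_order)) {
      present <- keep_order[keep_order %in% tb$level]
      tb <- tb[match(c(present, setdiff(tb$level, present)), level)]
    }
    if (!is.null(top_k)) tb <- utils::head(tb, top_k)
    tb[, pct := pct_half_up(n, denom)]
    tb[, section := section]
    tb[, .(section, level, n, pct)]
  }

  # sex ---------------------------------------------------------------------
  sx <- toupper(trimws(demo$sex))
  sx[!sx %in% c("F", "M")] <- "Missing"
  sx[sx == "F"] <- "Female"; sx[sx == "M"] <- "Male"
  sex_tb <- count_block("Sex", sx, keep_order = c("Female", "Male", "Missing"))

  # age ---------------------------------------------------------------------
  yrs <- age_in_years(demo$age, demo$age_cod)
  ab <- age_bin_label(yrs, age_cuts)
  ab[ab == "missing"] <- "Missing"
  ord <- c(sprintf("<%d", age_cuts[1]),
           sprintf("%d-<%d", age_cuts[1], age_cuts[2]),
           sprintf(">=%d", age_cuts[2]), "Missing")
  age_tb <- count_block("Age", ab, keep_order = ord)

  # outcomes ----------------------------------------------------------------
  oc <- cases$outcomes[cases$outcomes$primaryid %in% ids]
  oc <- unique(data.table::data.table(primaryid = oc$primaryid,
                                      code = toupper(trimws(oc$outc_cod))))
  oc <- oc[code != ""]
  lab <- .OUTCOME_LABELS[oc$code]
  lab[is.na(lab)] <- oc$code[is.na(lab)]
  n_missing_outc <- n_total - length(unique(oc$primaryid))
  out_tb <- count_block("Outcome", c(lab, rep("Missing", n_missing_outc)),
                        keep_order = c(unname(.OUTCOME_LABELS), "Missing"))

  # indications (denominator: total indication entries) ----------------------
  ind <- cases$indications[cases$indications$primaryid %in% ids]
  ind_terms <- squish(ind$indi_pt)
  ind_terms <- ind_terms[ind_terms != ""]
  ind_tb <- count_block(sprintf("Indications (top %d)", top_indications),
                        ind_terms, denom = length(ind_terms),
                        top_k = top_indications)

  # reporter occupation ------------------------------------------------------
  occ <- toupper(trimws(demo$occp_cod))
  occ_lab <- .OCCP_LABELS[occ]
  occ_lab[is.na(occ_lab) & occ != ""] <- occ[is.na(occ_lab) & occ != ""]
  occ_lab[occ == ""] <- "Missing"
  rep_tb <- count_block("Reported person", occ_lab)

  # reporter country ---------------------------------------------------------
  ctry <- squish(demo$occr_country)
  ctry[ctry == ""] <- "Missing"
  ctry_tb <- count_block(sprintf("Reported countries (top %d)", top_countries),
                         ctry, top_k = top_countries)

  # receipt year -------------------------------------------------------------
  yr <- substr(trimws(demo$fda_dt), 1, 4)
  yr[!grepl("^[0-9]{4}$", yr)] <- "Missing"
  yr_tb <- count_block("Year", yr)
  yr_tb <- yr_tb[order(level)]

  out <- data.table::rbindlist(
    list(sex_tb, age_tb, out_tb, ind_tb, rep_tb, ctry_tb, yr_tb))
  data.table::setattr(out, "n_total", n_total)
  data.table::setattr(out, "class", c("faers_table1", class(out)))
  out[]
}
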