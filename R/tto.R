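# Time to onset: days from therapy start (THER.start_dt) to event onset
# (DEMO.event_dt), with explicit exclusion statuses instead of silent drops.

.TTO_STATUSES <- c("included", "excluded_missing", "excluded_partial_date",
                   "excluded_event_before_start")

#' Compute time to onset for start/event date pairs
#'
#' Both dates must be full, valid 8-digit `YYYYMMDD` strings to be included;
#' the onset interval is the calendar-day difference (the start date is
#' day 0). Every input yields exactly one status:
#' blank or missing date on either side -> `excluded_missing`;
#' a present but partial (4- or 6-digit) or calendar-invalid date ->
#' `excluded_partial_date`;
#' event earlier than start -> `excluded_event_before_start`;
#' otherwise `included` with `days >= 0`.
#'
#' @param start_dt,event_dt character vectors of raw FAERS date strings.
#' @return data.table with `start_dt`, `event_dt`, `days` (integer, `NA`
#'   unless included) and `status`.
#' @export
#' @examples
#' compute_tto("20200101", "20200214") # 44 days, included
compute_tto <- function(start_dt, event_dt) {
  n <- max(length(start_dt), length(event_dt))
  s <- trimws(as.character(rep_len(start_dt, n)))
  e <- trimws(as.character(rep_len(event_dt, n)))
  s[is.na(s)] <- ""; e[is.na(e)] <- ""
  sd <- parse_faers_date(s)
  ed <- parse_faers_date(e)
  status <- rep("included", n)
  status[!is.na(sd) & !is.na(ed) & ed < sd] <- "excluded_event_before_start"
  status[(s != "" & is.na(sd)) | (e != "" & is.na(ed))] <- "excluded_partial_date"
  status[s == "" | e == ""] <- "excluded_missing"
  days <- rep(NA_integer_, n)
  inc <- status == "included"
  days[inc] <- as.integer(ed[inc] - sd[inc])
  data.table::data.table(start_dt = s, event_dt = e, days = days,
                         status = factor(status, levels = .TTO_STATUSES))
}

#' Per-report time to onset for the target-drug cohort
#'
#' One onset interval per cohort report: the start date is the earliest valid
#' therapy start among the report's target-drug rows (first initiation); a
#' report whose target drug has start dates but none valid is excluded as
#' partial, and one with no start information as missing. The event date comes
#' from the demographics table.
#'
#' @param cases deduplicated `faers_cases`.
#' @param cohort_ids primaryids of the cohort.
#' @param drug_terms,roles target-drug definition, as in [extract_cohort()].
#' @return data.table with `primaryid`, `start_dt`, `event_dt`, `days`,
#'   `status` (one row per cohort report).
#' @export
tto_records <- function(cases, cohort_ids, drug_terms, roles = "PS") {
  stopifnot(inherits(cases, "faers_cases"))
  dr <- cases$drugs[cases$drugs$primaryid %in% cohort_ids]
  dr <- dr[toupper(trimws(dr$role_cod)) %in% toupper(roles) &
             match_target_drug(dr$drugname, drug_terms)]
  th <- cases$ther[cases$ther$primaryid %in% cohort_ids]
  th <- th[dr, on = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq"),
           nomatch = NULL]
  pick_start <- function(sdt) {
    sdt <- trimws(sdt)
    d <- parse_faers_date(sdt)
    if (any(!is.na(d))) return(sdt[which.min(d)]) # earliest valid start
    nz <- sdt[sdt != ""]
    if (length(nz)) nz[1] else ""
  }
  starts <- th[, .(start_dt = pick_start(start_dt)), by = primaryid]
  demo <- cases$demo[cases$demo$primaryid %in% cohort_ids,
                     c("primaryid", "event_dt")]
  x <- merge(demo, starts, by = "primaryid", all.x = TRUE)
  x[is.na(start_dt), start_dt := ""]
  res <- compute_tto(x$start_dt, x$event_dt)
  out <- data.table::data.table(primaryid = x$primaryid, res)
  out[order(id_order_key(primaryid))]
}

#' Summarize onset intervals
#'
#' Median and interquartile range over included records (linear-interpolation,
#' type-7 quantiles — stated because the values depend on the convention) and
#' counts per onset bin. Default bins are closed integer-day intervals
#' 0-30, 31-60, 61-90, 91-180, 181-365 and >365, so day 0 and day 30 both fall
#' in the first month.
#'
#' @param x a [tto_records()] / [compute_tto()] table, or a numeric vector of
#'   included onset days.
#' @param breaks upper edges of the finite bins (days).
#' @return a `tto_summary` list: `n_included`, `excluded` (counts by reason),
#'   `median`, `q1`, `q3`, and `bins` (data.table bin/n/pct, percentages of
#'   included records, half-up to 2 decimals).
#' @export
summarize_tto <- function(x, breaks = c(30, 60, 90, 180, 365)) {
  if (is.numeric(x)) {
    days <- x[!is.na(x)]
    excl <- c(excluded_missing = 0L, excluded_partial_date = 0L,
              excluded_event_before_start = 0L)
  } else {
    x <- data.table::as.data.table(x)
    days <- x$days[x$status == "included"]
    excl <- vapply(.TTO_STATUSES[-1], function(st) sum(x$status == st),
                   integer(1))
  }
  stopifnot(all(diff(breaks) > 0), all(breaks > 0))
  n_inc <- length(days)
  qs <- if (n_inc) unname(stats::quantile(days, c(.25, .5, .75), type = 7))
        else rep(NA_real_, 3)
  lab <- c(sprintf("0-%d", breaks[1]),
           sprintf("%d-%d", utils::head(breaks, -1) + 1, breaks[-1]),
           sprintf(">%d", breaks[length(breaks)]))
  idx <- findInterval(days, c(breaks + 1L)) + 1L
  bins <- data.table::data.table(
    bin = factor(lab, levels = lab),
    n = as.integer(tabulate(idx, nbins = length(lab))))
  bins[, pct := pct_half_up(n, n_inc)]
  structure(list(n_included = n_inc, excluded = excl,
                 median = qs[2], q1 = qs[1], q3 = qs[3], bins = bins),
            class = "tto_summary")
}

#' @export
print.tto_summary <- function(x, ...) {
  cat(sprintf("<tto_summary> n=%d, median %s days (IQR %s-%s)\n",
              x$n_included, format(x$median), format(x$q1), format(x$q3)))
  print(x$bins)
  invisible(x)
}
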