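# Four-compartment tables and the frequentist / Bayesian disproportionality
# statistics, with the per-algorithm significance criteria.

#' Build four-compartment contingency tables
#'
#' For every term (preferred term or system organ class) with at least one
#' cohort pair, counts the 2x2 table over unique (report, term) pairs across
#' the full deduplicated database:
#' `a` = cohort reports with the term, `b` = other cohort pairs,
#' `c` = background reports with the term, `d` = other background pairs.
#' `N = a+b+c+d` is identical for every term at a given level, and
#' `E = (a+b)(a+c)/N` is the expected count under independence used by the
#' empirical-Bayes shrinker.
#'
#' @param event_rows coded event table from [code_events()] over the full
#'   database (cohort and background).
#' @param cohort_ids primaryids of the target-drug cohort.
#' @param level `"PT"` or `"SOC"`: the term a table is built for. At SOC level
#'   a report contributes one pair per distinct SOC.
#' @return data.table with `term`, `soc` (at PT level), `a`, `b`, `c`, `d`,
#'   `N`, `E`, ordered by descending `a`.
#' @export
build_contingency <- function(event_rows, cohort_ids, level = c("PT", "SOC")) {
  level <- match.arg(level)
  ev <- data.table::as.data.table(event_rows)
  if (nrow(ev) == 0L) {
    return(data.table::data.table(term = character(0), soc = character(0),
                                  a = integer(0), b = integer(0),
                                  c = integer(0), d = integer(0),
                                  N = integer(0), E = numeric(0)))
  }
  if (level == "PT") {
    pairs <- unique(ev[, .(primaryid, term = pt, soc)])
  } else {
    pairs <- unique(ev[, .(primaryid, term = soc)])
    pairs[, soc := term]
  }
  pairs[, in_cohort := primaryid %in% cohort_ids]
  N <- nrow(pairs)
  n_target <- sum(pairs$in_cohort)
  tab <- pairs[, .(a = sum(in_cohort), n_term = .N, soc = soc[1L]), by = term]
  tab[, `:=`(b = n_target - a, c = n_term - a)]
  tab[, d := N - n_target - c]
  tab <- tab[a >= 1L]
  tab[, `:=`(N = N, E = as.numeric(a + b) * as.numeric(a + c) / N,
             n_term = NULL)]
  data.table::setorderv(tab, c("a", "term"), order = c(-1L, 1L))
  tab[, .(term, soc, a, b, c, d, N, E)]
}

#' Reporting odds ratio with Woolf 95 percent confidence interval
#'
#' `ROR = ad/(bc)`; `CI = exp(log ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))`.
#' Tables with any zero cell are non-evaluable and return `NA` (no Haldane
#' correction is applied; the `a >= 3` signal criterion gates such tables out
#' anyway).
#'
#' @param a,b,c,d vectors of cell counts.
#' @return data.table with `ror`, `ror_low`, `ror_high`.
#' @export
ror_stat <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ror_low <- ror_high <- rep(NA_real_, length(a))
  ror[ok] <- (a[ok] * d[ok]) / (b[ok] * c[ok])
  se <- sqrt(1 / a[ok] + 1 / b[ok] + 1 / c[ok] + 1 / d[ok])
  ror_low[ok] <- exp(log(ror[ok]) - 1.96 * se)
  ror_high[ok] <- exp(log(ror[ok]) + 1.96 * se)
  data.table::data.table(ror = ror, ror_low = ror_low, ror_high = ror_high)
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is Pearson's on
#' the 2x2 table, without continuity correction by default:
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`. Tables with a zero margin are
#' non-evaluable (`NA`).
#'
#' @param a,b,c,d vectors of cell counts.
#' @param yates apply the Yates continuity correction to the chi-squared
#'   statistic (default `FALSE`; published FAERS analyses differ, so the
#'   choice is an explicit switch).
#' @return data.table with `prr`, `chi2`.
#' @export
prr_stat <- function(a, b, c, d, yates = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  ok <- (a + b) > 0 & (c + d) > 0 & (a + c) > 0 & (b + d) > 0
  prr <- chi2 <- rep(NA_real_, length(a))
  prr[ok] <- (a[ok] / (a[ok] + b[ok])) / (c[ok] / (c[ok] + d[ok]))
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(dev - N / 2, 0)
  chi2[ok] <- (N[ok] * dev[ok]^2) /
    ((a[ok] + b[ok]) * (c[ok] + d[ok]) * (a[ok] + c[ok]) * (b[ok] + d[ok]))
  data.table::data.table(prr = prr, chi2 = chi2)
}

#' BCPNN information component (closed form)
#'
#' The information component is the Bayesian log2 ratio of the observed to
#' expected joint reporting probability. This is the closed-form posterior
#' approximation with the standard weak priors (alpha1 = beta1 = 1,
#' alpha = beta = 2, gamma11 = 1, and gamma tuned so the prior expectation of
#' the joint probability is the product of the margins). `ic025` is
#' `E(IC) - 2 sd(IC)`, the conventional lower credibility bound.
#'
#' @param a,b,c,d vectors of cell counts.
#' @return data.table with `ic` (posterior expectation) and `ic025`.
#' @export
bcpnn_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  n1. <- a + b
  n.1 <- a + c
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gam <- g11 * (N + al) * (N + be) / ((n1. + a1) * (n.1 + b1))
  eic <- log2((a + g11) * (N + al) * (N + be) /
                ((N + gam) * (n1. + a1) * (n.1 + b1)))
  vic <- ((N - a + gam - g11) / ((a + g11) * (1 + N + gam)) +
            (N - n1. + al - a1) / ((n1. + a1) * (1 + N + al)) +
            (N - n.1 + be - b1) / ((n.1 + b1) * (1 + N + be))) / log(2)^2
  data.table::data.table(ic = eic, ic025 = eic - 2 * sqrt(vic))
}

#' Signal retention criteria
#'
#' The standard published thresholds for the four algorithms:
#' ROR: `a >= 3` and lower 95 percent CI bound `> 1`;
#' PRR: `a >= 3`, `PRR >= 2`, `chi2 >= 4`;
#' BCPNN: `IC025 > 0`;
#' MGPS: `EB05 > 2`.
#' A term is retained when the rule is satisfied: `"all"` (default) requires
#' all four flags, `"any"` requires at least `n_required` of them (the
#' combined-criteria reading is configurable because "significant across four
#' algorithms" is ambiguous in common usage).
#'
#' @param min_a minimum case count for ROR/PRR evaluability.
#' @param ror_ci_low,prr_min,chi2_min,ic025_min,eb05_min thresholds.
#' @param rule `"all"` or `"any"`.
#' @param n_required number of flags needed under `rule = "any"`.
#' @param yates pass the Yates correction switch through to [prr_stat()].
#' @return a `signal_criteria` list.
#' @export
signal_criteria <- function(min_a = 3, ror_ci_low = 1, prr_min = 2,
                            chi2_min = 4, ic025_min = 0, eb05_min = 2,
                            rule = c("all", "any"), n_required = 4,
                            yates = FALSE) {
  rule <- match.arg(rule)
  stopifnot(min_a >= 0, n_required >= 1, n_required <= 4)
  structure(list(min_a = min_a, ror_ci_low = ror_ci_low, prr_min = prr_min,
                 chi2_min = chi2_min, ic025_min = ic025_min,
                 eb05_min = eb05_min, rule = rule, n_required = n_required,
                 yates = yates),
            class = "signal_criteria")
}

#' Apply the per-algorithm flags and the combined retention rule
#'
#' A non-evaluable statistic (`NA`, e.g. from a zero cell) yields a `FALSE`
#' flag, never an error.
#'
#' @param stats data.table carrying `a`, `ror_low`, `prr`, `chi2`, `ic025`,
#'   `eb05` columns (as produced inside [screen_signals()]).
#' @param criteria a [signal_criteria()] object.
#' @return the input with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `flag_mgps` and `retained` added.
#' @export
evaluate_criteria <- function(stats, criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  x <- data.table::as.data.table(stats)
  f <- function(v) !is.na(v) & v
  x[, flag_ror := f(a >= criteria$min_a & ror_low > criteria$ror_ci_low)]
  x[, flag_prr := f(a >= criteria$min_a & prr >= criteria$prr_min &
                      chi2 >= criteria$chi2_min)]
  x[, flag_bcpnn := f(ic025 > criteria$ic025_min)]
  x[, flag_mgps := f(eb05 > criteria$eb05_min)]
  nflags <- x$flag_ror + x$flag_prr + x$flag_bcpnn + x$flag_mgps
  x[, retained := if (criteria$rule == "all") nflags == 4L
                  else nflags >= criteria$n_required]
  x[]
}

#' Screen a database for disproportionality signals
#'
#' Builds the contingency tables at the requested level, computes all four
#' statistics for every term with `a >= 1` (fitting the MGPS prior across the
#' level's tables unless one is supplied), applies the retention criteria and
#' returns the full ranked table — retained and non-retained terms alike, with
#' per-algorithm flags, so "significant in at least one algorithm" views can
#' be derived. Output is ordered by SOC, then descending case count.
#'
#' @param event_rows coded event table from [code_events()].
#' @param cohort_ids primaryids of the target-drug cohort.
#' @param level `"PT"` or `"SOC"`.
#' @param criteria a [signal_criteria()] object.
#' @param prior optional pre-fitted [fit_mgps_prior()] result.
#' @return a `signal_screen` data.table: term, soc, the 2x2 counts, `ror` with
#'   CI, `prr` with `chi2`, `ic` with `ic025`, `ebgm` with `eb05`, flags and
#'   `retained`; attributes `prior` and `criteria`.
#' @export
screen_signals <- function(event_rows, cohort_ids, level = c("PT", "SOC"),
                           criteria = signal_criteria(), prior = NULL) {
  level <- match.arg(level)
  tab <- build_contingency(event_rows, cohort_ids, level)
  if (nrow(tab) == 0L) {
    res <- tab[, `:=`(ror = numeric(0))] # degenerate empty screen
    return(structure(res, class = c("signal_screen", class(res)),
                     prior = prior, criteria = criteria, level = level))
  }
  tab <- cbind(tab, ror_stat(tab$a, tab$b, tab$c, tab$d))
  tab <- cbind(tab, prr_stat(tab$a, tab$b, tab$c, tab$d, yates = criteria$yates))
  tab <- cbind(tab, bcpnn_ic(tab$a, tab$b, tab$c, tab$d))
  if (is.null(prior)) prior <- fit_mgps_prior(tab$a, tab$E)
  tab <- cbind(tab, ebgm_stat(tab$a, tab$E, prior))
  tab <- evaluate_criteria(tab, criteria)
  data.table::setorderv(tab, c("soc", "a", "term"), order = c(1L, -1L, 1L))
  data.table::setattr(tab, "prior", prior)
  data.table::setattr(tab, "criteria", criteria)
  data.table::setattr(tab, "level", level)
  data.table::setattr(tab, "class", c("signal_screen", class(tab)))
  tab[]
}
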