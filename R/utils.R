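# internal helpers shared across modules

fs_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "faersignal_error", "error", "condition")))
}

#' Round half away from zero
#'
#' Decimal rounding with halves always rounded up in magnitude (so 0.425 at
#' 2 digits is 0.43, not base R's banker's 0.42). Used for every reported
#' percentage so printed tables are reproducible.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(42.0237, 36.895) * 1, 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by a relative epsilon so values stored just below an exact half
  # (floating point) still round up
  z <- floor(abs(x) * p + 0.5 + abs(x) * .Machine$double.eps * 8)
  sign(x) * z / p
}

pct_half_up <- function(n, denom, digits = 2) {
  if (length(denom) == 1L && (is.na(denom) || denom <= 0)) {
    return(rep(0, length(n)))
  }
  round_half_up(100 * n / denom, digits)
}

# collapse internal whitespace, trim, uppercase: identity used for PT and
# mapping keys (FAERS REAC preferred terms vary in case and spacing)
normalize_term <- function(x) {
  x <- toupper(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# squish whitespace but keep original case (display form of a PT)
squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# drug names: uppercase and collapse every punctuation/whitespace run to one
# space, so "FTD/TPI", "FTD\\TPI" and "ftd tpi" compare equal
normalize_drug <- function(x) {
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

is_full_date_string <- function(x) {
  !is.na(x) & grepl("^[0-9]{8}$", x)
}

# strict YYYYMMDD parse: anything but a valid 8-digit calendar date is NA
parse_faers_date <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(as.Date(NA), length(x))
  ok <- is_full_date_string(x)
  if (any(ok)) out[ok] <- as.Date(x[ok], format = "%Y%m%d")
  out
}

format_faers_date <- function(d) format(d, "%Y%m%d")

# order caseids / primaryids numerically when they are digit strings,
# lexicographically otherwise (FAERS ids are numeric in practice)
id_order_key <- function(x) {
  suppressWarnings(num <- as.numeric(x))
  if (anyNA(num)) rank(x, ties.method = "min") else num
}

# age in years from FAERS age + age_cod
AGE_FACTORS <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.18,
                 DY = 1 / 365.25, HR = 1 / 8766)

age_in_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- AGE_FACTORS[toupper(trimws(age_cod))]
  f[is.na(f) & !is.na(v) & trimws(age_cod) == ""] <- 1 # bare number: assume years
  unname(v * f)
}

age_bin_label <- function(years, cuts = c(18, 65)) {
  stopifnot(length(cuts) == 2, cuts[1] < cuts[2])
  out <- rep("missing", length(years))
  ok <- !is.na(years)
  out[ok & years < cuts[1]] <- sprintf("<%d", cuts[1])
  out[ok & years >= cuts[1] & years < cuts[2]] <- sprintf("%d-<%d", cuts[1], cuts[2])
  out[ok & years >= cuts[2]] <- sprintf(">=%d", cuts[2])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
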