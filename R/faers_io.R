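# FAERS-dialect ASCII i/o: "$"-delimited, one header line, no quoting.

.FAERS_TABLE_IDS <- c("DEMO", "DRUG", "REAC", "OUTC", "RPSR", "THER", "INDI")

.FAERS_SCHEMAS <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "event_dt", "sex", "age",
           "age_cod", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
  REAC = c("primaryid", "caseid", "pt"),
  OUTC = c("primaryid", "caseid", "outc_cod"),
  RPSR = c("primaryid", "caseid", "rpsr_cod"),
  THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt"),
  INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt")
)

#' FAERS table schema
#'
#' Minimal column schema for one of the seven FAERS quarterly ASCII tables
#' (demographics DEMO, drugs DRUG, reactions REAC, outcomes OUTC, report
#' sources RPSR, therapy dates THER, indications INDI). Column sets cover what
#' the downstream cohort, signal and time-to-onset stages consume; unknown
#' extra columns in a file are preserved but ignored.
#'
#' @param table_id one of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`, `"RPSR"`,
#'   `"THER"`, `"INDI"` (case-insensitive).
#' @return a list with `table_id`, `columns` (required column names, lower
#'   case) and `key_fields` (`primaryid`, `caseid`).
#' @export
faers_schema <- function(table_id) {
  table_id <- toupper(table_id)
  if (!table_id %in% .FAERS_TABLE_IDS) {
    fs_error(sprintf("unknown FAERS table id '%s' (expected one of %s)",
                     table_id, paste(.FAERS_TABLE_IDS, collapse = ", ")),
             "faers_usage_error")
  }
  list(table_id = table_id,
       columns = .FAERS_SCHEMAS[[table_id]],
       key_fields = c("primaryid", "caseid"))
}

# read a text file as UTF-8, falling back to latin-1 re-encoding when the
# bytes are not valid UTF-8 (legacy FAERS quarters)
read_lines_fallback <- function(path) {
  raw <- readLines(path, warn = FALSE, encoding = "UTF-8")
  bad <- !validUTF8(raw)
  if (any(bad)) {
    raw[bad] <- iconv(raw[bad], from = "latin1", to = "UTF-8")
  }
  raw
}

# split "$"-delimited lines without dropping trailing empty fields
split_dollar <- function(lines) {
  if (length(lines) == 0L) return(list())
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

#' Read a FAERS quarterly ASCII table
#'
#' Parses one "$"-delimited FAERS table. The first line must be a header
#' naming the columns; the header drives column order and is validated against
#' the table schema (FAERS column sets drift across quarters, so extra columns
#' are kept but ignored). No field is type-coerced at this layer: dates, ages
#' and counts stay raw strings so no row can be lost silently to a parse
#' failure.
#'
#' @param path path to the ASCII file.
#' @param table_id FAERS table id, see [faers_schema()].
#' @return a `data.table` of character columns named as in the (lower-cased)
#'   header, plus a `line_no` column (1-based file line), with attribute
#'   `table_id`.
#' @export
read_faers_table <- function(path, table_id) {
  schema <- faers_schema(table_id)
  if (!file.exists(path)) {
    fs_error(sprintf("file does not exist: %s", path), "faers_usage_error")
  }
  lines <- read_lines_fallback(path)
  if (length(lines) == 0L) {
    fs_error(sprintf("%s: empty file (no header line)", path),
             "faers_dialect_error")
  }
  header <- tolower(split_dollar(lines[1])[[1]])
  missing_cols <- setdiff(schema$columns, header)
  if (length(missing_cols)) {
    fs_error(sprintf(
      "%s: header does not satisfy %s schema.\n  header columns: %s\n  schema columns: %s\n  missing: %s",
      path, schema$table_id, paste(header, collapse = ", "),
      paste(schema$columns, collapse = ", "),
      paste(missing_cols, collapse = ", ")), "faers_schema_error")
  }
  body <- split_dollar(lines[-1])
  nf <- lengths(body)
  bad <- which(nf != length(header))
  if (length(bad)) {
    fs_error(sprintf(
      "%s: line %d has %d fields, header has %d",
      path, bad[1] + 1L, nf[bad[1]], length(header)), "faers_dialect_error")
  }
  if (length(body)) {
    dt <- data.table::setDT(data.table::transpose(body))
    data.table::setnames(dt, header)
  } else {
    dt <- data.table::setDT(
      stats::setNames(replicate(length(header), character(0), simplify = FALSE),
                      header))
  }
  if (nrow(dt) && any(trimws(dt$primaryid) == "")) {
    fs_error(sprintf("%s: empty primaryid at line %d", path,
                     which(trimws(dt$primaryid) == "")[1] + 1L),
             "faers_dialect_error")
  }
  dt[, line_no := .I + 1L]
  data.table::setattr(dt, "table_id", schema$table_id)
  dt[]
}

#' Write a FAERS quarterly ASCII table
#'
#' Emits a header line plus one "$"-joined line per record; the output is
#' byte-stable given identical input and round-trips through
#' [read_faers_table()].
#'
#' @param x a `data.table` of character columns with a `table_id` attribute
#'   (as returned by [read_faers_table()] or built by the synthetic
#'   generator); a `line_no` column, if present, is dropped.
#' @param path output file path.
#' @param table_id optional override of `attr(x, "table_id")`.
#' @return `path`, invisibly.
#' @export
write_faers_table <- function(x, path, table_id = NULL) {
  table_id <- table_id %||% attr(x, "table_id")
  if (is.null(table_id)) {
    fs_error("no table_id attribute on records and none supplied",
             "faers_usage_error")
  }
  if (!is.null(x[["table_id"]]) && length(unique(x[["table_id"]])) > 1L) {
    fs_error("records mix more than one table_id", "faers_usage_error")
  }
  faers_schema(table_id) # validates the id
  cols <- setdiff(names(x), c("line_no", "table_id"))
  lines <- c(paste(cols, collapse = "$"))
  if (nrow(x)) {
    lines <- c(lines, do.call(paste, c(unname(as.list(x[, cols, with = FALSE])),
                                       sep = "$")))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a set of FAERS tables to a directory
#'
#' @param tables named list of tables (names are FAERS table ids).
#' @param dir output directory, created if needed.
#' @return named character vector of file paths, invisibly.
#' @export
write_faers_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- toupper(names(tables))
  paths <- file.path(dir, paste0(ids, ".txt"))
  for (i in seq_along(tables)) {
    write_faers_table(tables[[i]], paths[i], table_id = ids[i])
  }
  invisible(stats::setNames(paths, ids))
}

#' Read a directory of FAERS tables
#'
#' Looks for one file per FAERS table whose name starts with the table id
#' (case-insensitive), e.g. `DEMO.txt` or `demo23q1.txt`.
#'
#' @param dir directory containing the seven "$"-delimited tables.
#' @param required table ids that must be present (default DEMO, DRUG, REAC).
#' @return named list of parsed tables.
#' @export
read_faers_tables <- function(dir, required = c("DEMO", "DRUG", "REAC")) {
  files <- list.files(dir, full.names = TRUE)
  out <- list()
  for (id in .FAERS_TABLE_IDS) {
    hit <- files[grepl(paste0("^", tolower(id)), tolower(basename(files)))]
    if (length(hit) == 0L) {
      if (id %in% toupper(required)) {
        fs_error(sprintf("no %s table found in %s", id, dir),
                 "faers_usage_error")
      }
      next
    }
    out[[id]] <- read_faers_table(hit[1], id)
  }
  out
}

#' Build a PT to SOC mapping from a data frame
#'
#' Keys are case-normalized with internal whitespace collapsed, matching how
#' reaction preferred terms are normalized before lookup. Duplicate rows are
#' tolerated when consistent; a preferred term mapped to two different system
#' organ classes is an error.
#'
#' @param df data frame whose first two columns are PT and SOC.
#' @return a `pt_soc_map`: data.table with `pt_key` and `soc`.
#' @export
as_pt_soc_map <- function(df) {
  if (ncol(df) < 2L) {
    fs_error("PT->SOC mapping needs two columns (PT, SOC)", "faers_usage_error")
  }
  m <- data.table::data.table(pt_key = normalize_term(as.character(df[[1]])),
                              soc = squish(as.character(df[[2]])))
  m <- unique(m)
  dup <- m[, .N, by = pt_key][N > 1L]
  if (nrow(dup)) {
    fs_error(sprintf("conflicting SOC mapping for PT(s): %s",
                     paste(dup$pt_key, collapse = ", ")),
             "ptsoc_conflict_error")
  }
  data.table::setkey(m, pt_key)
  data.table::setattr(m, "class", c("pt_soc_map", class(m)))
  m[]
}

#' Load a PT to SOC mapping file
#'
#' Two-column delimited text (CSV or TSV, header required): preferred term,
#' system organ class. MedDRA itself is licensed, so the dictionary content is
#' always user-supplied.
#'
#' @param path path to the mapping file.
#' @return a `pt_soc_map`, see [as_pt_soc_map()].
#' @export
load_pt_soc_map <- function(path) {
  if (!file.exists(path)) {
    fs_error(sprintf("mapping file does not exist: %s", path),
             "faers_usage_error")
  }
  df <- data.table::fread(path, header = TRUE, colClasses = "character")
  as_pt_soc_map(df)
}

#' Look up system organ classes for preferred terms
#'
#' @param map a `pt_soc_map`.
#' @param pts character vector of preferred terms (any case/spacing).
#' @return character vector of SOC names, `NA` where the PT is unmapped
#'   (unmapped terms are never dropped silently: downstream coding tallies
#'   them under `"UNMAPPED"`).
#' @export
soc_for_pt <- function(map, pts) {
  stopifnot(inherits(map, "pt_soc_map"))
  map$soc[match(normalize_term(pts), map$pt_key)]
}
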