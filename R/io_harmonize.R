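# Canonical household schema ---------------------------------------------

#' Canonical household-record column names
#'
#' Every loader maps survey-specific variable names onto this schema; all
#' downstream operations (indicator classification, estimation, regression)
#' consume it. Monetary fields are annual amounts in a common currency.
#'
#' @return Character vector of required column names.
#' @export
household_fields <- function() {
  c("household_id", "survey_id", "wave_year", "urban", "province",
    "family_size", "income_total", "consumption_total",
    "food_expenditure", "oop_health_expenditure", "weight")
}

.monetary_fields <- c("income_total", "consumption_total",
                      "food_expenditure", "oop_health_expenditure")

# Dialects ---------------------------------------------------------------

#' Construct a survey dialect map
#'
#' A dialect describes how one survey's raw export maps onto the canonical
#' household schema: which source column holds each field, which source
#' fields are reported per month (annualized by x12 at load), and free-text
#' notes recording known concept differences (e.g. whether dietary
#' supplements are counted inside out-of-pocket health spending). Concept
#' differences are recorded, never reconciled.
#'
#' @param survey_id label for the survey (e.g. "cfps").
#' @param column_map named character vector: names are canonical field names,
#'   values are source column names. Must cover every canonical field.
#' @param monthly_fields canonical field names reported monthly at source.
#' @param notes free text.
#' @return An object of class `dialect_map`.
#' @export
dialect_map <- function(survey_id, column_map, monthly_fields = character(),
                        notes = "") {
  stopifnot(is.character(column_map), length(survey_id) == 1L)
  missing <- setdiff(household_fields(), names(column_map))
  # survey_id and wave_year may be supplied as constants rather than columns
  missing <- setdiff(missing, c("survey_id", "wave_year"))
  if (length(missing))
    stop("dialect '", survey_id, "' column_map misses required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- setdiff(monthly_fields, household_fields())
  if (length(bad))
    stop("unknown monthly field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(survey_id = survey_id, column_map = column_map,
                 monthly_fields = monthly_fields, notes = notes),
            class = "dialect_map")
}

#' Built-in survey dialects
#'
#' Shipped mappings for the four national household surveys the package is
#' designed around plus the `"canonical"` identity dialect (a file already in
#' the canonical schema round-trips bit-for-bit). The source column names for
#' the four registration-gated surveys are placeholders shipped as editable
#' YAML (see [read_dialect()]); the monthly-food convention and the
#' out-of-pocket concept notes follow each survey's questionnaire design:
#' two of the surveys collect food spending per month, and their health
#' spending concepts differ (one includes exercise and dietary supplements,
#' another is pure out-of-pocket).
#'
#' @param survey_id one of "canonical", "cfps", "cgss", "chfs", "css".
#' @return A [dialect_map()].
#' @export
builtin_dialect <- function(survey_id = c("canonical", "cfps", "cgss",
                                          "chfs", "css")) {
  survey_id <- match.arg(survey_id)
  ident <- stats::setNames(household_fields(), household_fields())
  switch(survey_id,
    canonical = dialect_map("canonical", ident),
    cfps = dialect_map("cfps", c(
      household_id = "fid", survey_id = "survey", wave_year = "year",
      urban = "urban", province = "provcd", family_size = "familysize",
      income_total = "fincome", consumption_total = "expense",
      food_expenditure = "food_month", oop_health_expenditure = "med_oop",
      weight = "fswt_natcs"),
      monthly_fields = "food_expenditure",
      notes = "food reported monthly; OOP includes exercise and dietary supplements"),
    cgss = dialect_map("cgss", c(
      household_id = "id", survey_id = "survey", wave_year = "year",
      urban = "urban", province = "prov", family_size = "famsize",
      income_total = "inc_total", consumption_total = "cons_total",
      food_expenditure = "food_year", oop_health_expenditure = "health_oop",
      weight = "wt"),
      notes = "food includes market value of home-grown farm products"),
    chfs = dialect_map("chfs", c(
      household_id = "hhid", survey_id = "survey", wave_year = "year",
      urban = "rural_urban", province = "prov_code", family_size = "hh_size",
      income_total = "total_income", consumption_total = "total_consumption",
      food_expenditure = "food_monthly", oop_health_expenditure = "health_exp",
      weight = "swgt"),
      monthly_fields = "food_expenditure",
      notes = "food reported monthly; health spending includes exercise, supplements, fitness"),
    css = dialect_map("css", c(
      household_id = "caseid", survey_id = "survey", wave_year = "year",
      urban = "urban", province = "province", family_size = "fam_n",
      income_total = "hh_income", consumption_total = "hh_consumption",
      food_expenditure = "hh_food", oop_health_expenditure = "hh_oop_health",
      weight = "weight_cs"),
      notes = "pure out-of-pocket health spending, outpatient + inpatient"))
}

#' Read or write a dialect map as YAML/JSON config
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_dialect()` returns a [dialect_map()]; `write_dialect()`
#'   returns `path` invisibly.
#' @export
read_dialect <- function(path) {
  cfg <- .read_config(path)
  dialect_map(cfg$survey_id, unlist(cfg$column_map),
              monthly_fields = as.character(unlist(cfg$monthly_fields)),
              notes = if (is.null(cfg$notes)) "" else cfg$notes)
}

#' @rdname read_dialect
#' @param dialect a [dialect_map()].
#' @export
write_dialect <- function(dialect, path) {
  x <- list(survey_id = dialect$survey_id,
            column_map = as.list(dialect$column_map),
            monthly_fields = dialect$monthly_fields, notes = dialect$notes)
  .write_config(x, path)
}

.read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

.write_config <- function(x, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                            digits = NA)
  invisible(path)
}

# CPI series -------------------------------------------------------------

#' Consumer price index series for currency rebasing
#'
#' @param index named numeric vector, names are calendar years, values a CPI
#'   on any common base (only ratios matter). All values must be positive.
#' @param reference_year year whose prices everything is rebased to; must be
#'   present in `index`.
#' @return An object of class `cpi_series`.
#' @export
cpi_series <- function(index, reference_year) {
  stopifnot(is.numeric(index), !is.null(names(index)))
  if (any(index <= 0)) stop("CPI index values must be positive", call. = FALSE)
  reference_year <- as.integer(reference_year)
  if (!as.character(reference_year) %in% names(index))
    stop("reference year ", reference_year, " absent from CPI series",
         call. = FALSE)
  structure(list(index = index, reference_year = reference_year),
            class = "cpi_series")
}

#' @rdname cpi_series
#' @param path YAML or JSON file with fields `index` (year -> value) and
#'   `reference_year`.
#' @export
read_cpi <- function(path) {
  cfg <- .read_config(path)
  cpi_series(unlist(cfg$index), cfg$reference_year)
}

# Loading ----------------------------------------------------------------

#' Load survey microdata under a dialect
#'
#' Reads a delimited text file (delimiter auto-detected among comma, tab and
#' semicolon unless given), renames columns per the dialect, annualizes
#' monthly fields by x12, coerces numerics, and drops rows with missing or
#' unparseable required values (complete-case analysis, counted in the load
#' report).
#'
#' @param path delimited text file with a header row.
#' @param dialect a [dialect_map()].
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @param survey_id,wave_year constants used when the dialect does not map a
#'   source column for them.
#' @return A `data.frame` of canonical household records with attribute
#'   `"load_report"` (list: `source_rows`, `dropped_missing`, `rows_loaded`).
#' @export
load_survey <- function(path, dialect = builtin_dialect("canonical"),
                        sep = NULL, survey_id = NULL, wave_year = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .sniff_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  cm <- dialect$column_map
  mapped <- intersect(names(cm), household_fields())
  for (f in mapped) {
    if (!cm[[f]] %in% names(raw))
      stop("dialect '", dialect$survey_id, "': source column '", cm[[f]],
           "' (mapped to ", f, ") not found in header of ", path,
           call. = FALSE)
  }
  out <- stats::setNames(as.data.frame(raw[, cm[mapped], drop = FALSE],
                                       stringsAsFactors = FALSE), mapped)
  if (!"survey_id" %in% names(out))
    out$survey_id <- if (is.null(survey_id)) dialect$survey_id else survey_id
  if (!"wave_year" %in% names(out)) {
    if (is.null(wave_year))
      stop("dialect maps no wave_year column and no wave_year constant given",
           call. = FALSE)
    out$wave_year <- wave_year
  }
  numeric_fields <- setdiff(household_fields(), c("household_id", "survey_id",
                                                  "province"))
  for (f in numeric_fields) out[[f]] <- suppressWarnings(as.numeric(out[[f]]))
  out$wave_year <- as.integer(out$wave_year)
  for (f in dialect$monthly_fields) out[[f]] <- out[[f]] * 12
  required <- setdiff(household_fields(), "household_id")
  keep <- !Reduce(`|`, lapply(out[required], is.na))
  keep[is.na(keep)] <- FALSE
  dropped <- sum(!keep)
  out <- out[keep, household_fields(), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "load_report") <- list(source_rows = nrow(raw),
                                   dropped_missing = dropped,
                                   rows_loaded = nrow(out))
  out
}

.sniff_sep <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("\t" = lengths(regmatches(header, gregexpr("\t", header))),
              ","  = lengths(regmatches(header, gregexpr(",", header))),
              ";"  = lengths(regmatches(header, gregexpr(";", header))))
  if (all(counts == 0)) return(",")
  names(counts)[which.max(counts)]
}

#' Write a harmonized table to canonical CSV
#'
#' Round-trip guarantee: `load_survey(write_households(x, p))` with the
#' canonical dialect reproduces all fields.
#'
#' @param records canonical household table.
#' @param path output CSV path.
#' @export
write_households <- function(records, path) {
  utils::write.csv(records[, household_fields(), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Validation -------------------------------------------------------------

#' Validate household records
#'
#' Hard invariants remove the row (counted): negative monetary amounts,
#' `family_size < 1`, nonpositive weight, missing required values. A soft
#' rule flags but keeps rows whose food spending exceeds total consumption
#' (inconsistent reporting is common in raw survey data; removal would bias
#' incidence, and a nonpositive capacity to pay is handled explicitly by the
#' indicator rules).
#'
#' @param records canonical household table.
#' @return list with `records` (cleaned table, plus logical column
#'   `food_exceeds_consumption`) and `report` (named counts per rule).
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  n0 <- nrow(records)
  required <- setdiff(household_fields(), "household_id")
  miss <- Reduce(`|`, lapply(records[required], is.na))
  neg <- rep(FALSE, n0)
  for (f in .monetary_fields)
    neg <- neg | (!is.na(records[[f]]) & records[[f]] < 0)
  bad_size <- !is.na(records$family_size) & records$family_size < 1
  bad_wt <- !is.na(records$weight) & records$weight <= 0
  remove <- miss | neg | bad_size | bad_wt
  remove[is.na(remove)] <- TRUE
  out <- records[!remove, , drop = FALSE]
  out$food_exceeds_consumption <-
    out$food_expenditure > out$consumption_total
  rownames(out) <- NULL
  report <- list(
    input_rows = n0,
    missing_required = sum(miss, na.rm = TRUE),
    negative_amount = sum(neg & !miss),
    family_size_lt_1 = sum(bad_size & !miss & !neg),
    nonpositive_weight = sum(bad_wt & !miss & !neg & !bad_size),
    removed = sum(remove),
    food_exceeds_consumption = sum(out$food_exceeds_consumption),
    rows_kept = nrow(out))
  list(records = out, report = report)
}

# Currency rebasing ------------------------------------------------------

#' Rebase monetary fields to reference-year prices
#'
#' Each monetary field is multiplied by `cpi[reference_year] / cpi[wave_year]`
#' so that all waves are expressed in comparable reference-year prices.
#' Within-record ratios (hence all CHE flags) are invariant to rebasing;
#' records already in the reference year are untouched.
#'
#' @param records canonical household table.
#' @param cpi a [cpi_series()].
#' @return The table with monetary fields rebased.
#' @export
rebase_currency <- function(records, cpi) {
  stopifnot(inherits(cpi, "cpi_series"))
  yrs <- as.character(records$wave_year)
  missing_yrs <- setdiff(unique(yrs), names(cpi$index))
  if (length(missing_yrs))
    stop("CPI series missing year(s): ", paste(missing_yrs, collapse = ", "),
         call. = FALSE)
  factor <- unname(cpi$index[[as.character(cpi$reference_year)]] /
                   cpi$index[yrs])
  for (f in .monetary_fields) records[[f]] <- records[[f]] * factor
  records
}
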