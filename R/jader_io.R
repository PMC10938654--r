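#' Column-name dialect for the four JADER-style tables
#'
#' The public JADER distribution uses Japanese column headers; synthetic and
#' translated extracts use English snake_case. The dialect maps the canonical
#' field names used internally to the column names present in the files.
#'
#' @param demo,drug,reac,hist Named character vectors mapping canonical field
#'   names to file column names.
#' @return List of class `jader_dialect`.
#' @export
jader_dialect <- function(demo = c(case_id = "case_id", sex = "sex", age = "age",
                                   reporting_year = "reporting_year"),
                          drug = c(case_id = "case_id", drug_name = "drug_name",
                                   role_code = "role_code",
                                   daily_dose_g = "daily_dose_g",
                                   start_date = "start_date"),
                          reac = c(case_id = "case_id", pt_code = "pt_code",
                                   pt_name = "pt_name", onset_date = "onset_date"),
                          hist = c(case_id = "case_id", disease_name = "disease_name")) {
  structure(list(demo = demo, drug = drug, reac = reac, hist = hist),
            class = "jader_dialect")
}

read_csv_chr <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE)
}

#' Parse a daily-dose string to grams
#'
#' Strips a trailing unit token ("g", full-width "g", surrounding whitespace)
#' and parses the remainder as a decimal number; anything else becomes
#' missing. Returns the numeric vector with attributes `n_unit_stripped` and
#' `n_unparseable`.
#' @param x Character vector of dose cells.
#' @keywords internal
parse_dose <- function(x) {
  raw <- trimws(x)
  stripped <- sub("[gｇ]\\s*$", "", raw)
  had_unit <- !is.na(raw) & nzchar(raw) & stripped != raw
  val <- suppressWarnings(as.numeric(stripped))
  val[!is.na(val) & val < 0] <- NA_real_
  unparseable <- !is.na(raw) & nzchar(raw) & is.na(val)
  structure(val, n_unit_stripped = sum(had_unit & !is.na(val)),
            n_unparseable = sum(unparseable))
}

#' Parse ISO dates, treating partial dates as missing
#'
#' Full `YYYY-MM-DD` strings become dates; JADER-style partial dates
#' (`YYYY` or `YYYY-MM`) and anything unparseable become `NA`, with partials
#' counted separately in the attributes.
#' @param x Character vector of date cells.
#' @keywords internal
parse_iso_date <- function(x) {
  raw <- trimws(x)
  full <- !is.na(raw) & grepl("^\\d{4}-\\d{2}-\\d{2}$", raw)
  partial <- !is.na(raw) & grepl("^\\d{4}(-\\d{2})?$", raw)
  val <- rep(as.Date(NA), length(x))
  suppressWarnings(val[full] <- as.Date(raw[full]))
  full <- full & !is.na(val)  # e.g. 2020-02-31 fails to parse
  structure(val, n_partial = sum(partial),
            n_invalid = sum(!is.na(raw) & nzchar(raw) & !full & !partial))
}

require_columns <- function(df, cols, file, table) {
  missing <- setdiff(unname(cols), names(df))
  if (length(missing)) {
    abort(sprintf("%s table (%s): missing required column(s): %s",
                  table, file, paste(missing, collapse = ", ")))
  }
}

#' Read the four JADER-dialect tables
#'
#' Reads and type-coerces the demographic, drug, reaction and history tables.
#' Unparseable dose or date cells become missing (never silently dropped);
#' the returned bundle carries a parse report counting coerced cells.
#'
#' @param demo,drug,reac,hist File paths.
#' @param dialect A [jader_dialect()].
#' @return A list of class `jader_bundle` with elements `demo`, `drug`,
#'   `reac`, `hist` (tibbles with canonical column names) and `parse_log`.
#' @export
read_tables <- function(demo, drug, reac, hist, dialect = jader_dialect()) {
  for (p in c(demo, drug, reac, hist)) {
    if (!file.exists(p)) abort(sprintf("read_tables: file not found: %s", p))
  }
  d <- dialect
  rename_to_canonical <- function(df, map) {
    df <- df[, unname(map), drop = FALSE]
    names(df) <- names(map)
    df
  }
  demo_df <- read_csv_chr(demo)
  require_columns(demo_df, d$demo, demo, "demo")
  demo_df <- rename_to_canonical(demo_df, d$demo)
  demo_df$reporting_year <- suppressWarnings(as.integer(demo_df$reporting_year))

  drug_df <- read_csv_chr(drug)
  require_columns(drug_df, d$drug, drug, "drug")
  drug_df <- rename_to_canonical(drug_df, d$drug)
  dose <- parse_dose(drug_df$daily_dose_g)
  start <- parse_iso_date(drug_df$start_date)
  drug_df$daily_dose_g <- as.numeric(dose)
  drug_df$start_date <- as.Date(start)

  reac_df <- read_csv_chr(reac)
  require_columns(reac_df, d$reac, reac, "reac")
  reac_df <- rename_to_canonical(reac_df, d$reac)
  onset <- parse_iso_date(reac_df$onset_date)
  reac_df$onset_date <- as.Date(onset)

  hist_df <- read_csv_chr(hist)
  require_columns(hist_df, d$hist, hist, "hist")
  hist_df <- rename_to_canonical(hist_df, d$hist)

  structure(list(demo = tibble::as_tibble(demo_df),
                 drug = tibble::as_tibble(drug_df),
                 reac = tibble::as_tibble(reac_df),
                 hist = tibble::as_tibble(hist_df),
                 parse_log = list(
                   dose_unit_stripped = attr(dose, "n_unit_stripped"),
                   dose_unparseable = attr(dose, "n_unparseable"),
                   start_date_partial = attr(start, "n_partial"),
                   start_date_invalid = attr(start, "n_invalid"),
                   onset_date_partial = attr(onset, "n_partial"),
                   onset_date_invalid = attr(onset, "n_invalid"))),
            class = "jader_bundle")
}

SEX_MAP <- c(male = "male", female = "female", m = "male", f = "female")
AGE_CANON <- c("10s" = "<20", "<20" = "<20", "20s" = "20s", "30s" = "30s",
               "40s" = "40s", "50s" = "50s", "60s" = "60s", "70s" = "70s",
               "80s or older" = "80s+", "80s+" = "80s+")

canon_sex <- function(x) unname(SEX_MAP[tolower(trimws(x))])

canon_age <- function(x) unname(AGE_CANON[trimws(x)])

#' Integrate the four tables into one report per case
#'
#' Collapses duplicate demographic rows per case id (the last occurrence in
#' file order wins, mirroring how resubmissions update an existing report),
#' drops child rows whose case id is absent from the demographic table (with
#' a logged count), and nests each case's drugs, events and history into one
#' row. Sex and age sentinels ("unknown", "aged") become missing.
#'
#' @param bundle A `jader_bundle` from [read_tables()].
#' @return A tibble with one row per case id and columns `case_id`, `sex`,
#'   `age_decade`, `reporting_year`, plus list-columns `drugs`, `events`,
#'   `history`; the integration log is in `attr(, "log")`.
#' @export
integrate_reports <- function(bundle) {
  stopifnot(inherits(bundle, "jader_bundle"))
  demo <- bundle$demo
  n_dup <- sum(duplicated(demo$case_id))
  demo <- demo[!duplicated(demo$case_id, fromLast = TRUE), , drop = FALSE]
  ids <- demo$case_id

  orphans <- c(drug = sum(!bundle$drug$case_id %in% ids),
               reac = sum(!bundle$reac$case_id %in% ids),
               hist = sum(!bundle$hist$case_id %in% ids))

  nest_by_case <- function(df, key) {
    df <- df[df$case_id %in% ids, , drop = FALSE]
    out <- tidyr::nest(df, !!key := !dplyr::all_of("case_id"))
    out
  }
  drugs <- nest_by_case(dplyr::rename(bundle$drug, name = "drug_name",
                                      role = "role_code"), "drugs")
  events <- nest_by_case(bundle$reac, "events")
  history <- bundle$hist[bundle$hist$case_id %in% ids, , drop = FALSE] |>
    dplyr::summarise(history = list(.data$disease_name), .by = "case_id")

  empty_drugs <- tibble::tibble(name = character(), role = character(),
                                daily_dose_g = numeric(),
                                start_date = as.Date(character()))
  empty_events <- tibble::tibble(pt_code = character(), pt_name = character(),
                                 onset_date = as.Date(character()))

  reports <- tibble::tibble(case_id = ids,
                            sex = canon_sex(demo$sex),
                            age_decade = canon_age(demo$age),
                            reporting_year = demo$reporting_year) |>
    dplyr::left_join(drugs, by = "case_id") |>
    dplyr::left_join(events, by = "case_id") |>
    dplyr::left_join(history, by = "case_id")
  reports$drugs <- lapply(reports$drugs, function(x) if (is.null(x)) empty_drugs else x)
  reports$events <- lapply(reports$events, function(x) if (is.null(x)) empty_events else x)
  reports$history <- lapply(reports$history, function(x) if (is.null(x)) character() else x)

  attr(reports, "log") <- list(n_demo_rows = nrow(bundle$demo),
                               n_reports = nrow(reports),
                               n_duplicate_demo = n_dup,
                               n_orphan_rows = orphans,
                               parse_log = bundle$parse_log)
  reports
}

#' Restrict each report's drug list to suspected drugs
#'
#' Concomitant and interacting drugs are removed from every report. Reports
#' left with no suspected drug are retained: they still contribute to the
#' whole-database background of the contingency tables.
#'
#' @param reports Integrated reports from [integrate_reports()].
#' @return The reports with filtered `drugs` list-column; the number of rows
#'   never changes.
#' @export
filter_suspected <- function(reports) {
  reports$drugs <- lapply(reports$drugs, function(d) d[d$role == "suspected", , drop = FALSE])
  reports
}

#' Exclude reports with incomplete demographics
#'
#' Drops reports whose required fields are missing (including the "unknown"
#' and "aged" sentinels, already mapped to `NA` at integration).
#'
#' @param reports Integrated reports.
#' @param require Character subset of `c("sex", "age")`.
#' @return The retained reports; `attr(, "exclusions")` holds the counts of
#'   input rows, rows missing each required field, and rows excluded.
#' @export
demographic_subset <- function(reports, require = c("sex", "age")) {
  require <- match.arg(require, c("sex", "age"), several.ok = TRUE)
  n_in <- nrow(reports)
  keep <- rep(TRUE, n_in)
  missing_counts <- integer(0)
  if ("sex" %in% require) {
    miss <- is.na(reports$sex)
    missing_counts["sex"] <- sum(miss)
    keep <- keep & !miss
  }
  if ("age" %in% require) {
    miss <- is.na(reports$age_decade)
    missing_counts["age"] <- sum(miss)
    keep <- keep & !miss
  }
  out <- reports[keep, , drop = FALSE]
  attr(out, "exclusions") <- list(n_input = n_in, n_excluded = n_in - nrow(out),
                                  missing = missing_counts)
  out
}

#' Flag reports with the target interstitial-lung-disease event
#'
#' A report is a case when any of its events carries the target preferred-term
#' code, or — as a fallback for extracts without codes — a preferred-term name
#' equal to "interstitial lung disease" case-insensitively. Event multiplicity
#' is ignored: one matching event suffices.
#'
#' @param reports Integrated reports.
#' @param pt_code Target MedDRA preferred-term code (default `"10022611"`).
#' @param pt_name Fallback preferred-term name.
#' @return Logical vector, one element per report.
#' @export
flag_diild <- function(reports, pt_code = DIILD_PT_CODE, pt_name = DIILD_PT_NAME) {
  vapply(reports$events, function(ev) {
    if (nrow(ev) == 0L) return(FALSE)
    any(!is.na(ev$pt_code) & ev$pt_code == pt_code) ||
      any(!is.na(ev$pt_name) & tolower(ev$pt_name) == tolower(pt_name))
  }, logical(1))
}
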