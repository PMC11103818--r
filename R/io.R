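#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr %>% n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median quantile rlnorm runif qnorm
#' @importFrom utils head
NULL

prescription_columns <- c(
  "prescription_id", "patient_id", "drug_name", "atc_code",
  "dose_mg_per_day", "route", "start_ts", "stop_ts",
  "indication_kind", "indication_focus", "indication_specification",
  "indication_free_text", "setting"
)

admission_columns <- c("admission_id", "patient_id", "admit_ts",
                       "discharge_ts", "via_er", "icu_stay", "age_years")

validation_columns <- c("course_id", "stratum", "indication_correct",
                        "indication_correct_site",
                        "lot_matches_prescriptions", "lot_matches_notes",
                        "error_cause")

course_columns <- c(
  "course_id", "patient_id",
  "definitive_kind", "definitive_focus", "definitive_specification",
  "start_ts", "stop_ts", "lot_days", "drug_names",
  "acquisition", "post_discharge_days", "exclusion_flags",
  "first_kind", "first_focus", "first_specification",
  "prescription_ids", "truncated_missing_stop",
  "multiple_final_diagnoses", "open_text_indication", "unlabeled",
  "admission_id", "pre_admission", "post_discharge_pct", "exclusion_reason"
)

read_raw_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), progress = FALSE,
                         show_col_types = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("%s file %s lacks required column(s): %s",
                  what, path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(raw), required)
  if (length(extra) > 0) {
    warn(sprintf("%s file %s: ignoring unrecognized column(s): %s",
                 what, path, paste(extra, collapse = ", ")))
  }
  raw[required]
}

check_ts_column <- function(x, parsed, col, what) {
  bad <- which(!is.na(x) & is.na(parsed))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed timestamp in column '%s' at data row(s) %s",
                  what, col, paste(utils::head(bad, 5), collapse = ", ")))
  }
}

check_required <- function(x, col, what) {
  bad <- which(is.na(x) | trimws(x) == "")
  if (length(bad) > 0) {
    abort(sprintf("%s: missing required value in column '%s' at data row(s) %s",
                  what, col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  x
}

parse_logical_column <- function(x, col, what) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-logical value in column '%s' at data row(s) %s",
                  what, col, paste(utils::head(bad, 5), collapse = ", ")))
  }
  out
}

#' Normalize registered indications against the controlled vocabulary
#'
#' Values outside the indication vocabulary are mapped to `open_text`
#' (the original text preserved in `indication_free_text`) with a
#' warning, mirroring how free-text entries escape a mandatory
#' registration tool. A specification is admissible only for UTI and RTI
#' foci.
#'
#' @param df tibble with indication_kind/focus/specification/free_text
#' @return df with normalized indication columns
#' @keywords internal
normalize_indications <- function(df, what = "prescriptions") {
  kind <- df$indication_kind
  focus <- df$indication_focus
  spec <- df$indication_specification
  free <- df$indication_free_text

  has_ind <- !is.na(kind)
  bad_kind <- has_ind & !(kind %in% indication_kinds)
  bad_focus <- has_ind & !bad_kind & kind != "open_text" &
    (!is.na(focus) & !(focus %in% focus_levels))
  bad_spec <- has_ind & !bad_kind & !bad_focus & !is.na(spec) &
    !((!is.na(focus) & focus == "UTI" & spec %in% uti_specifications) |
      (!is.na(focus) & focus == "RTI" & spec %in% rti_specifications))
  remap <- bad_kind | bad_focus | bad_spec
  if (any(remap)) {
    warn(sprintf("%s: %d indication(s) outside the controlled vocabulary mapped to open_text",
                 what, sum(remap)))
    free[remap] <- ifelse(is.na(free[remap]),
                          paste(dplyr::coalesce(kind[remap], ""),
                                dplyr::coalesce(focus[remap], ""),
                                dplyr::coalesce(spec[remap], "")),
                          free[remap])
    kind[remap] <- "open_text"
    focus[remap] <- NA_character_
    spec[remap] <- NA_character_
  }
  # open_text never carries a structured focus
  ot <- has_ind & kind == "open_text"
  focus[ot] <- NA_character_
  spec[ot] <- NA_character_
  df$indication_kind <- kind
  df$indication_focus <- focus
  df$indication_specification <- spec
  df$indication_free_text <- free
  df
}

#' Read an antibiotic prescription table
#'
#' Expects a UTF-8 comma-separated file with a header row and ISO 8601
#' timestamps at minute resolution (`"2020-06-01T13:30"`). Every
#' well-formed row yields one record with row order preserved; rows that
#' violate an invariant (malformed timestamp, stop before start, missing
#' required field) abort with the offending data row number, so no row
#' is ever silently dropped.
#'
#' @param path path to a prescriptions CSV
#' @param quiet suppress the row-count message
#' @return tibble with one row per prescription
#' @export
#' @examples
#' p <- write_prescriptions(example_prescriptions(), tempfile(fileext = ".csv"))
#' read_prescriptions(p, quiet = TRUE)
read_prescriptions <- function(path, quiet = FALSE) {
  raw <- read_raw_csv(path, prescription_columns, "prescriptions")
  what <- "prescriptions"
  check_required(raw$prescription_id, "prescription_id", what)
  check_required(raw$patient_id, "patient_id", what)
  check_required(raw$atc_code, "atc_code", what)
  check_required(raw$start_ts, "start_ts", what)
  start_ts <- parse_ts(raw$start_ts)
  stop_ts <- parse_ts(raw$stop_ts)
  check_ts_column(raw$start_ts, start_ts, "start_ts", what)
  check_ts_column(raw$stop_ts, stop_ts, "stop_ts", what)
  bad <- which(!is.na(stop_ts) & stop_ts < start_ts)
  if (length(bad) > 0) {
    abort(sprintf("prescriptions: stop_ts earlier than start_ts at data row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  dose <- suppressWarnings(as.numeric(raw$dose_mg_per_day))
  bad_dose <- which(!is.na(raw$dose_mg_per_day) & (is.na(dose) | dose < 0))
  if (length(bad_dose) > 0) {
    abort(sprintf("prescriptions: invalid dose_mg_per_day at data row(s) %s",
                  paste(utils::head(bad_dose, 5), collapse = ", ")))
  }
  route <- raw$route
  unk_route <- !is.na(route) & !(route %in% route_levels)
  if (any(unk_route)) {
    warn(sprintf("prescriptions: %d unknown route value(s) mapped to 'other'",
                 sum(unk_route)))
    route[unk_route] <- "other"
  }
  route[is.na(route)] <- "other"
  setting <- raw$setting
  unk_set <- !is.na(setting) & !(setting %in% setting_levels)
  if (any(unk_set)) {
    abort(sprintf("prescriptions: unknown setting value at data row(s) %s",
                  paste(utils::head(which(unk_set), 5), collapse = ", ")))
  }
  setting[is.na(setting)] <- "inpatient"

  out <- tibble(
    prescription_id = raw$prescription_id,
    patient_id = raw$patient_id,
    drug_name = raw$drug_name,
    atc_code = raw$atc_code,
    dose_mg_per_day = dose,
    route = route,
    start_ts = start_ts,
    stop_ts = stop_ts,
    indication_kind = raw$indication_kind,
    indication_focus = raw$indication_focus,
    indication_specification = raw$indication_specification,
    indication_free_text = raw$indication_free_text,
    setting = setting
  )
  out <- normalize_indications(out)
  if (!quiet) inform(sprintf("prescriptions: parsed %d record(s) from %s",
                             nrow(out), path))
  out
}

#' Write a prescription table
#'
#' Inverse of [read_prescriptions()]; `read(write(x))` reproduces `x`.
#'
#' @param prescriptions tibble as returned by [read_prescriptions()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_prescriptions <- function(prescriptions, path) {
  out <- prescriptions[prescription_columns]
  out$start_ts <- format_ts(out$start_ts)
  out$stop_ts <- format_ts(out$stop_ts)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a hospital admission table
#'
#' One row per hospitalization window with ER and ICU attributes and the
#' patient's age at admission. Discharge must be strictly after
#' admission.
#'
#' @param path path to an admissions CSV
#' @param quiet suppress the row-count message
#' @return tibble with one row per admission, including derived
#'   `duration_hours`
#' @export
read_admissions <- function(path, quiet = FALSE) {
  raw <- read_raw_csv(path, admission_columns, "admissions")
  what <- "admissions"
  check_required(raw$admission_id, "admission_id", what)
  check_required(raw$patient_id, "patient_id", what)
  check_required(raw$admit_ts, "admit_ts", what)
  check_required(raw$discharge_ts, "discharge_ts", what)
  admit_ts <- parse_ts(raw$admit_ts)
  discharge_ts <- parse_ts(raw$discharge_ts)
  check_ts_column(raw$admit_ts, admit_ts, "admit_ts", what)
  check_ts_column(raw$discharge_ts, discharge_ts, "discharge_ts", what)
  bad <- which(discharge_ts <= admit_ts)
  if (length(bad) > 0) {
    abort(sprintf("admissions: discharge_ts not after admit_ts at data row(s) %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  age <- suppressWarnings(as.numeric(raw$age_years))
  bad_age <- which(is.na(age) | age < 0)
  if (length(bad_age) > 0) {
    abort(sprintf("admissions: invalid age_years at data row(s) %s",
                  paste(utils::head(bad_age, 5), collapse = ", ")))
  }
  out <- tibble(
    admission_id = raw$admission_id,
    patient_id = raw$patient_id,
    admit_ts = admit_ts,
    discharge_ts = discharge_ts,
    via_er = parse_logical_column(raw$via_er, "via_er", what),
    icu_stay = parse_logical_column(raw$icu_stay, "icu_stay", what),
    age_years = age,
    duration_hours = as.numeric(difftime(discharge_ts, admit_ts, units = "hours"))
  )
  if (!quiet) inform(sprintf("admissions: parsed %d record(s) from %s",
                             nrow(out), path))
  out
}

#' Write a hospital admission table
#' @param admissions tibble as returned by [read_admissions()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_admissions <- function(admissions, path) {
  out <- admissions[admission_columns]
  out$admit_ts <- format_ts(out$admit_ts)
  out$discharge_ts <- format_ts(out$discharge_ts)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read reviewer verdicts for sampled courses
#'
#' Each record carries a reviewer's verdict on a sampled course: whether
#' the registered indication matched the clinical notes (overall and at
#' site level, i.e. forgiving UTI/RTI sub-type), whether the computed
#' LOT matched the prescriptions, whether it matched the notes, and — only
#' when it did not match the notes — the identified cause.
#'
#' @param path path to a validation CSV
#' @param quiet suppress the row-count message
#' @return tibble with one row per validated course
#' @export
read_validation <- function(path, quiet = FALSE) {
  raw <- read_raw_csv(path, validation_columns, "validation")
  what <- "validation"
  check_required(raw$course_id, "course_id", what)
  bad_str <- which(!is.na(raw$stratum) & !(raw$stratum %in% validation_strata))
  if (length(bad_str) > 0) {
    abort(sprintf("validation: unknown stratum at data row(s) %s",
                  paste(utils::head(bad_str, 5), collapse = ", ")))
  }
  lot_notes <- parse_logical_column(raw$lot_matches_notes, "lot_matches_notes", what)
  cause <- raw$error_cause
  bad_cause <- which(!is.na(cause) & !(cause %in% error_causes))
  if (length(bad_cause) > 0) {
    abort(sprintf("validation: unknown error_cause at data row(s) %s",
                  paste(utils::head(bad_cause, 5), collapse = ", ")))
  }
  orphan <- which(!is.na(cause) & lot_notes)
  if (length(orphan) > 0) {
    abort(sprintf("validation: error_cause present although LOT matches notes at data row(s) %s",
                  paste(utils::head(orphan, 5), collapse = ", ")))
  }
  ind_ok <- parse_logical_column(raw$indication_correct, "indication_correct", what)
  site_ok <- parse_logical_column(raw$indication_correct_site,
                                  "indication_correct_site", what)
  # a verdict correct at sub-type level is necessarily correct at site level
  miss <- is.na(site_ok)
  site_ok[miss] <- ind_ok[miss]
  site_ok[!is.na(ind_ok) & ind_ok] <- TRUE
  out <- tibble(
    course_id = raw$course_id,
    stratum = raw$stratum,
    indication_correct = ind_ok,
    indication_correct_site = site_ok,
    lot_matches_prescriptions = parse_logical_column(
      raw$lot_matches_prescriptions, "lot_matches_prescriptions", what),
    lot_matches_notes = lot_notes,
    error_cause = cause
  )
  if (!quiet) inform(sprintf("validation: parsed %d record(s) from %s",
                             nrow(out), path))
  out
}

#' Write reviewer verdicts
#' @param validation tibble as returned by [read_validation()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_validation <- function(validation, path) {
  out <- validation[validation_columns]
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write assembled treatment courses
#'
#' One row per course with the course metadata (patient id, final
#' diagnosis, start and stop date, total duration in calendar days, the
#' names of the antibiotics used, joined with ";"), plus acquisition
#' class, post-discharge days and any exclusion flags. Column order is
#' fixed, so repeated runs are byte-identical.
#'
#' @param courses course tibble (see [assemble_courses()] and
#'   [build_courses()])
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_courses <- function(courses, path) {
  out <- courses
  for (col in setdiff(course_columns, names(out))) {
    out[[col]] <- switch(col,
      lot_days = NA_integer_, post_discharge_days = NA_integer_,
      post_discharge_pct = NA_real_,
      acquisition = NA_character_, admission_id = NA_character_,
      exclusion_flags = "", exclusion_reason = NA_character_,
      pre_admission = NA,
      NA_character_)
  }
  out <- out[course_columns]
  out$start_ts <- format_ts(out$start_ts)
  out$stop_ts <- format_ts(out$stop_ts)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read back a written course table
#' @param path path to a courses CSV produced by [write_courses()]
#' @param quiet suppress the row-count message
#' @return course tibble
#' @export
read_courses <- function(path, quiet = FALSE) {
  raw <- read_raw_csv(path, course_columns, "courses")
  out <- as_tibble(raw)
  out$start_ts <- parse_ts(raw$start_ts)
  out$stop_ts <- parse_ts(raw$stop_ts)
  check_ts_column(raw$start_ts, out$start_ts, "start_ts", "courses")
  check_ts_column(raw$stop_ts, out$stop_ts, "stop_ts", "courses")
  for (col in c("lot_days", "post_discharge_days")) {
    out[[col]] <- as.integer(raw[[col]])
  }
  out$post_discharge_pct <- as.numeric(raw$post_discharge_pct)
  for (col in c("truncated_missing_stop", "multiple_final_diagnoses",
                "open_text_indication", "unlabeled", "pre_admission")) {
    out[[col]] <- parse_logical_column(raw[[col]], col, "courses")
  }
  out$exclusion_flags[is.na(out$exclusion_flags)] <- ""
  if (!quiet) inform(sprintf("courses: parsed %d record(s) from %s",
                             nrow(out), path))
  out
}

#' Write the exclusion flow table
#' @param flow tibble from [apply_exclusions()] (`step`, `n`)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_flow <- function(flow, path) {
  readr::write_csv(flow, path, na = "")
  invisible(path)
}

#' Write a surveillance summary table
#' @param summary tibble from [summarize_courses()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_summary <- function(summary, path) {
  readr::write_csv(summary, path, na = "")
  invisible(path)
}

#' A small worked prescription example
#'
#' Ten prescriptions for three patients illustrating the main assembly
#' behaviours: sequential linkage within 24 h, a prophylaxis-labelled
#' overlap, a trailing long-duration nitrofurantoin prescription and a
#' missing stop date.
#'
#' @return prescriptions tibble
#' @export
example_prescriptions <- function() {
  read_prescriptions(
    system.file("extdata", "example_prescriptions.csv", package = "lotsurv"),
    quiet = TRUE)
}

#' Admissions matching [example_prescriptions()]
#' @return admissions tibble
#' @export
example_admissions <- function() {
  read_admissions(
    system.file("extdata", "example_admissions.csv", package = "lotsurv"),
    quiet = TRUE)
}
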