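#' Controlled vocabularies used across the surveillance pipeline
#'
#' The indication vocabulary mirrors a mandatory EHR indication
#' registration tool: prescribers record whether a prescription is
#' empirical therapy, targeted therapy or prophylaxis, then select an
#' infection focus at tract level, with a further sub-type only for
#' urinary tract infections (UTI) and respiratory tract infections (RTI).
#'
#' @name lotsurv-vocab
#' @keywords internal
NULL

lot_tz <- "UTC"

indication_kinds <- c("empirical", "targeted", "prophylaxis", "open_text")

focus_levels <- c(
  "intra-abdominal", "UTI", "RTI", "bone/joint", "CNS", "ENT",
  "febrile neutropenia", "gastro-enteritis", "gynaecological", "CVL",
  "mediastinitis", "SAB", "sepsis e.c.i.", "skin/soft tissue", "other"
)

uti_specifications <- c("cystitis", "complicated", "kidney transplant",
                        "catheter-related", "other")

rti_specifications <- c("CAP-m", "CAP-s", "HAP", "COPD", "aspiration",
                        "abscess/empyema", "other")

route_levels <- c("oral", "intravenous", "other")

setting_levels <- c("inpatient", "outpatient", "er")

exclusion_reasons <- c(
  "not_hospital_initiated", "admission_under_12h", "pediatric",
  "icu_during_admission", "multiple_final_diagnoses",
  "open_text_indication", "duration_over_45d", "readmitted_during_course"
)

error_causes <- c("transfer", "pre_admission_start", "mislabeled_prophylaxis",
                  "opat", "single_dose_dosing", "other")

validation_strata <- c("UTI", "RTI", "IAI", "other", "extended")

#' Round half away from zero
#'
#' Percentages in surveillance reports are conventionally rounded half-up
#' to one decimal; base [round()] rounds half to even, which would turn
#' e.g. 20.85 into 20.8 rather than 20.9.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Parse ISO 8601 timestamps at minute resolution
#'
#' Accepts `"2020-06-01T13:30"` (also with seconds or a space separator)
#' and date-only `"2020-06-01"`, which is taken as midnight. A single
#' implicit timezone (UTC) is used throughout: the method works in
#' calendar days, so civil-time juggling adds nothing.
#'
#' @param x character vector
#' @return POSIXct vector; `NA` where the input is empty/NA
#' @keywords internal
parse_ts <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- rep(as.POSIXct(NA, tz = lot_tz), length(x))
  ok <- !is.na(x)
  if (!any(ok)) return(out)
  xi <- gsub("T", " ", trimws(x[ok]), fixed = TRUE)
  parsed <- as.POSIXct(strptime(xi, "%Y-%m-%d %H:%M:%S", tz = lot_tz))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(parsed)
    if (!any(miss)) break
    parsed[miss] <- as.POSIXct(strptime(xi[miss], fmt, tz = lot_tz))
  }
  out[ok] <- parsed
  out
}

format_ts <- function(ts) {
  ifelse(is.na(ts), NA_character_,
         format(ts, format = "%Y-%m-%dT%H:%M", tz = lot_tz))
}

ts_date <- function(ts) as.Date(ts, tz = lot_tz)

date_as_ts <- function(d) {
  as.POSIXct(as.numeric(unclass(d)) * 86400, origin = "1970-01-01", tz = lot_tz)
}

hours <- function(h) as.difftime(h, units = "hours")

#' Inclusive calendar-day span between two timestamps
#' @keywords internal
calendar_span_days <- function(start_ts, stop_ts) {
  as.integer(ts_date(stop_ts) - ts_date(start_ts)) + 1L
}
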