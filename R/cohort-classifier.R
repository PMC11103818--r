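#' Surveillance thresholds
#'
#' All tunable boundaries of the pipeline in one block: the maximum gap
#' (hours) allowed between a prior stop and the next start when linking
#' prescriptions into a course; the community-/hospital-acquired
#' boundary (hours from admission to treatment start); the minimum
#' admission duration counting as a hospitalization; the maximum course
#' duration retained for analysis (calendar days); and the adult age
#' boundary.
#'
#' @param gap_hours course-linkage gap, hours
#' @param ca_ha_boundary_hours CA/HA boundary, hours; exactly on the
#'   boundary classifies as HA
#' @param min_admission_hours minimum admission duration, hours
#' @param max_course_days longest course retained, calendar days
#' @param pediatric_age patients younger than this (years) are excluded
#' @return a named list of class `lot_thresholds`
#' @export
lot_thresholds <- function(gap_hours = 24, ca_ha_boundary_hours = 48,
                           min_admission_hours = 12, max_course_days = 45,
                           pediatric_age = 18) {
  stopifnot(gap_hours > 0, ca_ha_boundary_hours > 0,
            min_admission_hours > 0, max_course_days > 0, pediatric_age > 0)
  structure(list(gap_hours = gap_hours,
                 ca_ha_boundary_hours = ca_ha_boundary_hours,
                 min_admission_hours = min_admission_hours,
                 max_course_days = max_course_days,
                 pediatric_age = pediatric_age),
            class = "lot_thresholds")
}

#' Link each course to the admission during which it started
#'
#' A course is hospital-initiated when its start falls inside an
#' admission window (ER-initiated treatment links to the admission the
#' ER visit opened, since that window contains the start). Courses
#' started before admission but continuing into one — therapy begun in
#' the community, e.g. by a general practitioner — are linked to the
#' first overlapping admission and flagged `pre_admission` rather than
#' dropped. Courses touching no admission are flagged
#' `not_hospital_initiated`.
#'
#' @param courses course tibble
#' @param admissions admissions tibble
#' @return `courses` with `admission_id`, admission attributes,
#'   `pre_admission` and `not_hospital_initiated`
#' @export
attach_admissions <- function(courses, admissions) {
  check_no_overlap(admissions)
  adm_by_patient <- split(admissions, admissions$patient_id)
  n <- nrow(courses)
  admission_id <- rep(NA_character_, n)
  pre_admission <- rep(FALSE, n)
  for (i in seq_len(n)) {
    adms <- adm_by_patient[[courses$patient_id[i]]]
    if (is.null(adms) || nrow(adms) == 0) next
    s <- courses$start_ts[i]
    e <- courses$stop_ts[i]
    inside <- adms$admit_ts <= s & s <= adms$discharge_ts
    if (any(inside)) {
      admission_id[i] <- adms$admission_id[which(inside)[1]]
    } else {
      overlap <- s < adms$admit_ts & adms$admit_ts <= e
      if (any(overlap)) {
        j <- which(overlap)[order(adms$admit_ts[overlap])][1]
        admission_id[i] <- adms$admission_id[j]
        pre_admission[i] <- TRUE
      }
    }
  }
  courses$admission_id <- admission_id
  courses$pre_admission <- pre_admission
  courses$not_hospital_initiated <- is.na(admission_id)
  adm_cols <- admissions[c("admission_id", "admit_ts", "discharge_ts",
                           "via_er", "icu_stay", "age_years", "duration_hours")]
  courses <- dplyr::left_join(courses, adm_cols, by = "admission_id")
  courses
}

check_no_overlap <- function(admissions) {
  by_pat <- split(admissions, admissions$patient_id)
  for (adms in by_pat) {
    if (nrow(adms) < 2) next
    adms <- adms[order(adms$admit_ts), , drop = FALSE]
    if (any(adms$admit_ts[-1] < adms$discharge_ts[-nrow(adms)])) {
      abort(sprintf("admissions: overlapping admission windows for patient %s",
                    adms$patient_id[1]))
    }
  }
  invisible(TRUE)
}

#' Classify acquisition as community- or hospital-acquired
#'
#' An infection is community-acquired (CA) when antibiotic treatment
#' started less than `ca_ha_boundary_hours` (default 48 h) after
#' admission and hospital-acquired (HA) when it started later. Exactly
#' on the boundary classifies as HA — the conservative nosocomial
#' attribution. Courses started before admission are CA (they carry the
#' `pre_admission` flag from [attach_admissions()]); unlinked courses
#' remain `unclassified`.
#'
#' @param courses course tibble after [attach_admissions()]
#' @param thresholds a [lot_thresholds()] object
#' @return `courses` with an `acquisition` column (`CA`/`HA`/`unclassified`)
#' @export
classify_acquisition <- function(courses, thresholds = lot_thresholds()) {
  delta <- as.numeric(difftime(courses$start_ts, courses$admit_ts,
                               units = "hours"))
  courses$acquisition <- dplyr::case_when(
    is.na(courses$admission_id) ~ "unclassified",
    delta < thresholds$ca_ha_boundary_hours ~ "CA",
    TRUE ~ "HA"
  )
  courses
}

#' Length of treatment in calendar days
#'
#' LOT counts the calendar days during which antimicrobials were
#' consecutively prescribed for the definitive indication, including the
#' post-discharge period, irrespective of the number of agents or doses
#' on each day: the inclusive span from the start date to the stop date.
#'
#' @param courses course tibble
#' @return `courses` with `lot_days`
#' @export
compute_lot <- function(courses) {
  courses$lot_days <- calendar_span_days(courses$start_ts, courses$stop_ts)
  courses
}

#' Post-discharge share of each course
#'
#' Counts the course calendar days falling strictly after the discharge
#' date of the linked admission, and that count as a percentage of LOT.
#' A course ending on the discharge date has no post-discharge part; a
#' course lying entirely after discharge is 100% post-discharge.
#'
#' @param courses course tibble after [attach_admissions()] and
#'   [compute_lot()]
#' @return `courses` with `post_discharge_days` and `post_discharge_pct`
#' @export
compute_post_discharge <- function(courses) {
  after <- as.integer(ts_date(courses$stop_ts) - ts_date(courses$discharge_ts))
  days <- pmin(courses$lot_days, pmax(0L, after))
  days[is.na(courses$admission_id)] <- NA_integer_
  courses$post_discharge_days <- days
  courses$post_discharge_pct <- 100 * days / courses$lot_days
  courses
}

#' Apply the exclusion cascade
#'
#' Exclusion reasons are evaluated in a fixed order — not hospital
#' initiated, admission under the 12 h minimum, pediatric patient, ICU
#' stay during the admission, multiple final diagnoses, open-text
#' indication, course longer than 45 days, readmission during the
#' course — and each course is counted once, at its first matching
#' reason (criteria may overlap). The returned flow satisfies strict
#' count conservation: `n_input = n_remaining + sum(n_excluded)`. All
#' matching reasons are kept in `exclusion_flags` for inspection.
#'
#' A readmission only triggers exclusion when the new admission itself
#' qualifies as a hospitalization (meets the 12 h minimum) and admits
#' strictly within the course interval.
#'
#' @param courses course tibble after classification and measurement
#' @param admissions admissions tibble (for the readmission check)
#' @param thresholds a [lot_thresholds()] object
#' @param quiet suppress the flow message
#' @return list with `included` (courses retained), `excluded`,
#'   `courses` (all, annotated with `exclusion_reason`/`exclusion_flags`)
#'   and `flow` (tibble `step`, `n`)
#' @export
apply_exclusions <- function(courses, admissions,
                             thresholds = lot_thresholds(), quiet = FALSE) {
  n <- nrow(courses)
  adm_by_patient <- split(admissions, admissions$patient_id)
  readmitted <- vapply(seq_len(n), function(i) {
    adms <- adm_by_patient[[courses$patient_id[i]]]
    if (is.null(adms)) return(FALSE)
    qual <- adms$duration_hours >= thresholds$min_admission_hours
    own <- courses$admission_id[i]
    if (is.na(own)) own <- ""
    any(qual &
          adms$admission_id != own &
          adms$admit_ts > courses$start_ts[i] &
          adms$admit_ts < courses$stop_ts[i], na.rm = TRUE)
  }, logical(1))

  flags <- cbind(
    not_hospital_initiated = courses$not_hospital_initiated,
    admission_under_12h = !is.na(courses$duration_hours) &
      courses$duration_hours < thresholds$min_admission_hours,
    pediatric = !is.na(courses$age_years) &
      courses$age_years < thresholds$pediatric_age,
    icu_during_admission = !is.na(courses$icu_stay) & courses$icu_stay,
    multiple_final_diagnoses = courses$multiple_final_diagnoses,
    open_text_indication = courses$open_text_indication,
    duration_over_45d = courses$lot_days > thresholds$max_course_days,
    readmitted_during_course = readmitted
  )
  colnames(flags) <- exclusion_reasons
  first_reason <- apply(flags, 1, function(r) {
    hit <- which(r)
    if (length(hit) == 0) NA_character_ else exclusion_reasons[hit[1]]
  })
  if (n == 0) first_reason <- character(0)
  courses$exclusion_flags <- apply(flags, 1, function(r) {
    paste(exclusion_reasons[r], collapse = ";")
  })
  if (n == 0) courses$exclusion_flags <- character(0)
  courses$exclusion_reason <- first_reason

  counts <- table(factor(first_reason, levels = exclusion_reasons))
  n_remaining <- sum(is.na(first_reason))
  flow <- tibble(
    step = c("input", exclusion_reasons, "remaining"),
    n = c(n, as.integer(counts), n_remaining)
  )
  stopifnot(n == n_remaining + sum(as.integer(counts)))
  if (!quiet) {
    inform(sprintf("exclusions: %d course(s) in, %d excluded, %d remaining",
                   n, n - n_remaining, n_remaining))
  }
  list(
    included = courses[is.na(first_reason), , drop = FALSE],
    excluded = courses[!is.na(first_reason), , drop = FALSE],
    courses = courses,
    flow = flow
  )
}
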