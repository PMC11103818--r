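#' Prophylaxis rule set for unlabelled prescriptions
#'
#' Some prophylactic prescriptions reach the extract without a
#' prophylaxis label. They are recognised by drug-specific duration
#' thresholds: the listed agents are presumed prophylactic when
#' prescribed for more than 28 days, and trimethoprim/sulfamethoxazole
#' (co-trimoxazole) when prescribed at low daily dose (480 mg or lower)
#' for more than 14 days, or at higher doses for more than 50 days.
#' Duration is the inclusive calendar-day span of the prescription.
#'
#' @param long_term_drugs character vector of drug names for the 28-day rule
#' @param long_term_threshold_days duration threshold for those drugs
#' @param cotrimoxazole_low_dose_mg daily-dose boundary (mg) between the
#'   low- and high-dose co-trimoxazole rules
#' @param cotrimoxazole_low_dose_threshold_days duration threshold at low dose
#' @param cotrimoxazole_high_dose_threshold_days duration threshold at high dose
#' @return a list of class `prophylaxis_rules`
#' @export
prophylaxis_rules <- function(
    long_term_drugs = c("azithromycin", "clarithromycin", "doxycycline",
                        "erythromycin", "fosfomycin", "nitrofurantoin",
                        "pheneticillin", "trimethoprim"),
    long_term_threshold_days = 28L,
    cotrimoxazole_low_dose_mg = 480,
    cotrimoxazole_low_dose_threshold_days = 14L,
    cotrimoxazole_high_dose_threshold_days = 50L) {
  stopifnot(long_term_threshold_days > 0,
            cotrimoxazole_low_dose_mg > 0,
            cotrimoxazole_low_dose_threshold_days > 0,
            cotrimoxazole_high_dose_threshold_days >
              cotrimoxazole_low_dose_threshold_days)
  structure(list(
    long_term_drugs = tolower(long_term_drugs),
    long_term_threshold_days = as.integer(long_term_threshold_days),
    cotrimoxazole_low_dose_mg = cotrimoxazole_low_dose_mg,
    cotrimoxazole_low_dose_threshold_days =
      as.integer(cotrimoxazole_low_dose_threshold_days),
    cotrimoxazole_high_dose_threshold_days =
      as.integer(cotrimoxazole_high_dose_threshold_days)
  ), class = "prophylaxis_rules")
}

is_cotrimoxazole <- function(drug) {
  grepl("sulfamethoxazole|co-?trimoxazole", tolower(drug))
}

#' Classify unlabelled prescriptions as presumed prophylaxis
#'
#' Vectorized over the rows of `prescriptions`. Records without a stop
#' date are never presumed prophylaxis (their duration is unknown; the
#' missing-stop truncation rule handles them instead).
#'
#' @param prescriptions prescriptions tibble
#' @param rules a [prophylaxis_rules()] object
#' @return logical vector, one element per prescription
#' @export
is_presumed_prophylaxis <- function(prescriptions, rules = prophylaxis_rules()) {
  n <- nrow(prescriptions)
  if (n == 0) return(logical(0))
  dur <- rep(NA_integer_, n)
  has_stop <- !is.na(prescriptions$stop_ts)
  dur[has_stop] <- calendar_span_days(prescriptions$start_ts[has_stop],
                                      prescriptions$stop_ts[has_stop])
  drug <- tolower(trimws(prescriptions$drug_name))
  cotrim <- is_cotrimoxazole(drug)
  long_term <- drug %in% rules$long_term_drugs & !cotrim
  dose <- prescriptions$dose_mg_per_day
  low_dose <- !is.na(dose) & dose <= rules$cotrimoxazole_low_dose_mg

  out <- rep(FALSE, n)
  idx <- has_stop & long_term & dur > rules$long_term_threshold_days
  out[idx] <- TRUE
  idx_lo <- has_stop & cotrim & low_dose &
    dur > rules$cotrimoxazole_low_dose_threshold_days
  idx_hi <- has_stop & cotrim & !low_dose &
    dur > rules$cotrimoxazole_high_dose_threshold_days
  out[idx_lo | idx_hi] <- TRUE
  out
}

#' Keep only therapeutic antibiotic prescriptions
#'
#' Retains prescriptions whose ATC code begins with "J01" (systemic
#' antibacterials), that are not registered as prophylaxis, and that are
#' not presumed prophylaxis under the duration/dose rules. Prescriptions
#' registered as prophylaxis must be removed before assembly so they can
#' neither seed nor extend a treatment course.
#'
#' @param prescriptions prescriptions tibble
#' @param rules a [prophylaxis_rules()] object
#' @param quiet suppress per-reason removal counts
#' @return the retained prescriptions; removal counts in attribute
#'   `"removals"` (tibble `reason`, `n`)
#' @export
filter_therapeutic <- function(prescriptions, rules = prophylaxis_rules(),
                               quiet = FALSE) {
  non_j01 <- !startsWith(prescriptions$atc_code, "J01")
  labeled <- !non_j01 & !is.na(prescriptions$indication_kind) &
    prescriptions$indication_kind == "prophylaxis"
  presumed <- !non_j01 & !labeled & is.na(prescriptions$indication_kind) &
    is_presumed_prophylaxis(prescriptions, rules)
  removals <- tibble(
    reason = c("non_j01_atc", "labeled_prophylaxis", "presumed_prophylaxis"),
    n = c(sum(non_j01), sum(labeled), sum(presumed))
  )
  kept <- prescriptions[!(non_j01 | labeled | presumed), , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "therapeutic filter: kept %d of %d (removed %d non-J01, %d labelled prophylaxis, %d presumed prophylaxis)",
      nrow(kept), nrow(prescriptions), removals$n[1], removals$n[2], removals$n[3]))
  }
  attr(kept, "removals") <- removals
  kept
}

#' Effective stop timestamps under the missing-stop rule
#'
#' A prescription's effective stop is its stop timestamp when present;
#' when the stop date is missing (prescriptions incorrectly never
#' stopped), the prescription contributes only its start date — taken at
#' start of day, so a course ending on such a prescription is truncated
#' to the start date of its last prescription rather than extended.
#'
#' @param prescriptions prescriptions tibble
#' @return POSIXct vector of effective stops
#' @export
effective_stop <- function(prescriptions) {
  eff <- prescriptions$stop_ts
  miss <- is.na(eff)
  eff[miss] <- date_as_ts(ts_date(prescriptions$start_ts[miss]))
  eff
}

split_max <- function(x, f) {
  vapply(split(x, f), function(v) if (length(v)) max(v) else -Inf, numeric(1))
}

#' Assemble therapeutic prescriptions into treatment courses
#'
#' Per patient, prescriptions are sorted by start time (ties broken by
#' prescription id) and greedily linked: a prescription joins the open
#' course when it starts no more than `gap_hours` after the course's
#' latest effective stop (inclusive comparison, so a gap of exactly 24 h
#' still links); otherwise it opens a new course. Overlapping or nested
#' prescriptions therefore always share a course, and outpatient
#' prescriptions in the post-discharge period participate identically.
#' Course start/stop are the earliest member start and the latest member
#' effective stop.
#'
#' @param prescriptions therapeutic prescriptions tibble (see
#'   [filter_therapeutic()])
#' @param gap_hours maximum allowed gap between a prior stop and the next
#'   start, in hours
#' @param quiet suppress the course-count message
#' @return course tibble, one row per course, with first/definitive
#'   indications resolved; the member prescriptions annotated with
#'   `course_id` are available in attribute `"members"`
#' @export
assemble_courses <- function(prescriptions, gap_hours = 24, quiet = FALSE) {
  stopifnot(gap_hours >= 0)
  if (nrow(prescriptions) == 0) {
    courses <- empty_course_tibble()
    attr(courses, "members") <- dplyr::mutate(prescriptions,
                                              course_id = character(0))
    return(courses)
  }
  gap_secs <- gap_hours * 3600
  ord <- order(prescriptions$patient_id, prescriptions$start_ts,
               prescriptions$prescription_id)
  members <- prescriptions[ord, , drop = FALSE]
  eff_num <- as.numeric(effective_stop(members))
  start_num <- as.numeric(members$start_ts)
  pid <- members$patient_id
  n <- nrow(members)

  course_ord <- integer(n)
  cur_pat <- NA_character_
  cur <- -Inf
  k <- 0L
  for (i in seq_len(n)) {
    if (is.na(cur_pat) || pid[i] != cur_pat) {
      cur_pat <- pid[i]
      k <- 0L
      cur <- -Inf
    }
    if (start_num[i] > cur + gap_secs) {
      k <- k + 1L
      cur <- eff_num[i]
    } else {
      cur <- max(cur, eff_num[i])
    }
    course_ord[i] <- k
  }
  members$course_id <- paste0(pid, "-", course_ord)

  f <- factor(members$course_id, levels = unique(members$course_id))
  firsts <- !duplicated(f)
  miss <- is.na(members$stop_ts)
  stop_num <- split_max(eff_num, f)
  truncated <- split_max(ifelse(miss, eff_num, -Inf), f) >
    split_max(ifelse(miss, -Inf, eff_num), f)
  courses <- tibble(
    course_id = as.character(levels(f)),
    patient_id = pid[firsts],
    n_rx = as.integer(tabulate(f)),
    prescription_ids = unname(vapply(split(members$prescription_id, f),
                                     paste, "", collapse = ";")),
    drug_names = unname(vapply(split(members$drug_name, f),
                               function(x) paste(unique(x), collapse = ";"),
                               "")),
    start_ts = members$start_ts[firsts],
    stop_ts = as.POSIXct(unname(stop_num), tz = lot_tz, origin = "1970-01-01"),
    truncated_missing_stop = unname(truncated)
  )
  courses <- resolve_indications(courses, members)
  attr(courses, "members") <- members
  if (!quiet) inform(sprintf("assembled %d course(s) from %d prescription(s) for %d patient(s)",
                             nrow(courses), nrow(members),
                             dplyr::n_distinct(members$patient_id)))
  courses
}

empty_course_tibble <- function() {
  tibble(
    course_id = character(0), patient_id = character(0), n_rx = integer(0),
    prescription_ids = character(0), drug_names = character(0),
    start_ts = as.POSIXct(character(0), tz = lot_tz),
    stop_ts = as.POSIXct(character(0), tz = lot_tz),
    truncated_missing_stop = logical(0),
    first_kind = character(0), first_focus = character(0),
    first_specification = character(0),
    definitive_kind = character(0), definitive_focus = character(0),
    definitive_specification = character(0),
    multiple_final_diagnoses = logical(0), open_text_indication = logical(0),
    unlabeled = logical(0)
  )
}

indication_label <- function(kind, focus, spec) {
  paste(dplyr::coalesce(kind, "?"), dplyr::coalesce(focus, "?"),
        dplyr::coalesce(spec, ""), sep = "|")
}

#' Resolve first and definitive indications per course
#'
#' The indication of the earliest-starting member that carries one marks
#' the start of the course (the working diagnosis); the indication of
#' the latest-starting member with one is the definitive indication —
#' the course's final diagnosis. When several members share that latest
#' start time and carry more than one distinct indication the course is
#' flagged `multiple_final_diagnoses`; any open-text member flags
#' `open_text_indication`; a course with no indication at all is flagged
#' `unlabeled` (treated like an open-text indication by the exclusion
#' cascade).
#'
#' @param courses course tibble from [assemble_courses()]
#' @param members member prescriptions annotated with `course_id`
#' @return `courses` with indication columns filled in
#' @export
resolve_indications <- function(courses, members) {
  nc <- nrow(courses)
  f_all <- factor(members$course_id, levels = courses$course_id)
  o <- order(as.integer(f_all), members$start_ts, members$prescription_id)
  m <- members[o, , drop = FALSE]
  keep <- !is.na(m$indication_kind)
  lab <- m[keep, , drop = FALSE]
  fl <- factor(lab$course_id, levels = courses$course_id)
  li <- as.integer(fl)

  pick <- function(col, idx) {
    out <- rep(NA_character_, nc)
    out[li[idx]] <- lab[[col]][idx]
    out
  }
  first_idx <- which(!duplicated(li))
  last_idx <- which(!duplicated(li, fromLast = TRUE))
  courses$first_kind <- pick("indication_kind", first_idx)
  courses$first_focus <- pick("indication_focus", first_idx)
  courses$first_specification <- pick("indication_specification", first_idx)
  courses$definitive_kind <- pick("indication_kind", last_idx)
  courses$definitive_focus <- pick("indication_focus", last_idx)
  courses$definitive_specification <- pick("indication_specification", last_idx)

  start_num <- as.numeric(lab$start_ts)
  max_start <- split_max(start_num, fl)
  at_max <- start_num == max_start[li]
  labels <- indication_label(lab$indication_kind, lab$indication_focus,
                             lab$indication_specification)
  courses$multiple_final_diagnoses <- unname(vapply(
    split(labels[at_max], fl[at_max]),
    function(x) length(unique(x)) > 1, logical(1)))
  courses$open_text_indication <- unname(vapply(
    split(lab$indication_kind == "open_text", fl), any, logical(1)))
  courses$unlabeled <- tabulate(fl, nbins = nc) == 0
  # an unlabeled course is handled as open text downstream
  courses$open_text_indication <- courses$open_text_indication | courses$unlabeled
  courses
}
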