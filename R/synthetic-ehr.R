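r2m <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = lot_tz)
}

day_end <- function(d) date_as_ts(d) + (23 * 3600 + 59 * 60)

# validation-free tibble constructor for the generator's hot loop;
# recycles length-1 columns like tibble() but skips the checks
fast_tb <- function(...) {
  l <- list(...)
  n <- max(lengths(l))
  l <- lapply(l, function(x) if (length(x) == n) x else rep(x, length.out = n))
  tibble::new_tibble(l, nrow = n)
}

#' Reference LOT distribution per indication
#'
#' Default calibration table for the synthetic generator: per definitive
#' indication, the relative frequency and the median and interquartile
#' range of the length of treatment (calendar days), separately for
#' community- and hospital-acquired infections. The values reflect the
#' indication mix and treatment durations typical of hospital-wide
#' antibiotic surveillance in a large teaching hospital; they drive the
#' generator's indication weights and its discretized log-normal LOT
#' distributions.
#'
#' @return tibble with one row per indication (focus + specification)
#' @export
lot_reference <- function() {
  tibble::tribble(
    ~focus, ~specification, ~ca_n, ~ca_med, ~ca_q1, ~ca_q3, ~ha_n, ~ha_med, ~ha_q1, ~ha_q3,
    "intra-abdominal", NA, 1191, 6, 4, 9, 435, 6, 4, 10,
    "RTI", "CAP-m", 672, 6, 4, 8, 71, 6, 4, 7,
    "RTI", "CAP-s", 215, 5, 3, 7, 23, 5, 3.5, 6,
    "RTI", "HAP", 126, 6, 4, 8, 234, 6, 4, 8,
    "RTI", "COPD", 147, 7, 3, 8, 33, 6, 3, 8,
    "RTI", "aspiration", 175, 7, 3, 9, 88, 7, 5, 9,
    "RTI", "abscess/empyema", 50, 14.5, 6.3, 24.8, 14, 33, 16.8, 41.5,
    "RTI", "other", 302, 6, 3, 9, 72, 6.5, 4.8, 8.3,
    "UTI", "cystitis", 845, 6, 2, 9, 505, 6, 4, 8,
    "UTI", "complicated", 544, 11, 5, 15, 106, 11, 6, 15,
    "UTI", "kidney transplant", 144, 14, 7, 15, 40, 11, 4.8, 15.3,
    "UTI", "catheter-related", 87, 9, 3, 15, 64, 7, 4, 11,
    "UTI", "other", 193, 8, 3, 14, 42, 6.5, 2, 11.8,
    "bone/joint", NA, 470, 8, 2, 16, 97, 8, 3, 16,
    "CNS", NA, 112, 7, 3, 14.3, 35, 8, 6.5, 12.5,
    "ENT", NA, 212, 10, 7, 13, 90, 9, 6, 11,
    "febrile neutropenia", NA, 59, 5, 3, 6.5, 123, 4, 4, 6,
    "gastro-enteritis", NA, 105, 5, 3, 9, 39, 6, 3, 9.5,
    "gynaecological", NA, 377, 2, 1, 8, 78, 2, 1, 5,
    "CVL", NA, 108, 6, 3, 11, 74, 5, 3, 8,
    "mediastinitis", NA, 48, 8, 3, 15, 14, 8.5, 7, 14.8,
    "SAB", NA, 67, 13, 8, 18.5, 22, 15.5, 12, 16,
    "sepsis e.c.i.", NA, 717, 4, 2, 7, 319, 5, 3, 7,
    "skin/soft tissue", NA, 672, 11, 6, 15, 195, 10, 6, 13
  )
}

drug_catalog <- function() {
  tibble::tribble(
    ~drug_name, ~atc_code,
    "amoxicillin/clavulanic acid", "J01CR02",
    "ceftriaxone", "J01DD04",
    "cefuroxime", "J01DC02",
    "ciprofloxacin", "J01MA02",
    "meropenem", "J01DH02",
    "piperacillin/tazobactam", "J01CR05",
    "flucloxacillin", "J01CF05",
    "gentamicin", "J01GB03",
    "vancomycin", "J01XA01",
    "ceftazidime", "J01DD02",
    "amoxicillin", "J01CA04"
  )
}

long_term_catalog <- function() {
  tibble::tribble(
    ~drug_name, ~atc_code,
    "nitrofurantoin", "J01XE01",
    "trimethoprim", "J01EA01",
    "doxycycline", "J01AA02",
    "azithromycin", "J01FA10",
    "clarithromycin", "J01FA09",
    "erythromycin", "J01FA01",
    "fosfomycin", "J01XX01",
    "pheneticillin", "J01CE05"
  )
}

#' Configuration for the synthetic EHR generator
#'
#' Each patient receives one admission and one intended treatment
#' course; noise scenarios are layered on top at the given rates. The
#' scenarios mirror the data-complexity patterns of hospital-acquired
#' infection records: a prophylaxis-labelled prescription overlapping
#' the course (`b1`), an unlabelled long-duration prophylactic
#' prescription trailing the course (`b2`), an unrelated
#' prophylaxis-labelled prescription starting mid-course (`b3`),
#' prescriptions with a missing stop date, open-text indications,
#' multiple final diagnoses, pediatric and ICU admissions, admissions
#' under 12 h, readmission during the course, extended (> 45 day)
#' courses, courses started before admission, and non-antibacterial
#' (non-J01) prescriptions. Default rates make every scenario appear
#' roughly 20+ times per 1000 patients so each behaviour is testable.
#'
#' @param n_patients number of patients (one intended course each)
#' @param seed integer seed; generation is deterministic given the config
#' @param cai_fraction probability a course is community-acquired
#' @param reference calibration table, see [lot_reference()]
#' @param post_discharge_rate_ca,post_discharge_rate_ha probability that
#'   part of the course falls after discharge
#' @param working_diagnosis_rate probability the first registered
#'   indication is a working diagnosis (sepsis e.c.i.) later revised
#' @param rates named list of scenario rates (see Details)
#' @return a validated list of class `sim_config`
#' @export
simulation_config <- function(n_patients = 1000, seed = 20200601,
                              cai_fraction = 0.73,
                              reference = lot_reference(),
                              post_discharge_rate_ca = 0.375,
                              post_discharge_rate_ha = 0.237,
                              working_diagnosis_rate = 0.15,
                              rates = list()) {
  defaults <- list(
    b1 = 0.05, b2 = 0.03, b3 = 0.03, missing_stop = 0.04, non_j01 = 0.05,
    open_text = 0.03, multi_final = 0.02, pediatric = 0.03, icu = 0.05,
    short_admission = 0.02, readmission = 0.02, over_45d = 0.02,
    pre_admission = 0.02
  )
  unknown <- setdiff(names(rates), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown scenario rate(s): %s", paste(unknown, collapse = ", ")))
  }
  defaults[names(rates)] <- rates
  probs <- c(cai_fraction, post_discharge_rate_ca, post_discharge_rate_ha,
             working_diagnosis_rate, unlist(defaults))
  if (any(probs < 0 | probs > 1)) abort("all rates must be probabilities in [0, 1]")
  excl <- c("open_text", "multi_final", "pediatric", "icu", "short_admission",
            "readmission", "over_45d", "pre_admission")
  if (sum(unlist(defaults[excl])) >= 1) {
    abort("exclusive scenario rates must sum to less than 1")
  }
  if (n_patients < 1) abort("n_patients must be positive")
  w <- reference$ca_n + reference$ha_n
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    cai_fraction = cai_fraction, reference = reference,
    weights = w / sum(w),
    post_discharge_rate_ca = post_discharge_rate_ca,
    post_discharge_rate_ha = post_discharge_rate_ha,
    working_diagnosis_rate = working_diagnosis_rate,
    rates = defaults
  ), class = "sim_config")
}

draw_lot <- function(ref_row, is_ca) {
  med <- if (is_ca) ref_row$ca_med else ref_row$ha_med
  q1 <- if (is_ca) ref_row$ca_q1 else ref_row$ha_q1
  q3 <- if (is_ca) ref_row$ca_q3 else ref_row$ha_q3
  sdlog <- (log(q3) - log(q1)) / (2 * stats::qnorm(0.75))
  max(1L, as.integer(round(stats::rlnorm(1, meanlog = log(med), sdlog = sdlog))))
}

# Split a course interval into k member prescriptions whose gaps never
# exceed 24 h, preserving the exact course start and stop.
split_members <- function(start_ts, stop_ts, k) {
  span_min <- as.numeric(difftime(stop_ts, start_ts, units = "mins"))
  if (span_min < 2 * k) k <- 1L
  if (k == 1) {
    return(fast_tb(start_ts = start_ts, stop_ts = stop_ts))
  }
  cuts_min <- sort(sample(seq_len(span_min - 1), k - 1))
  cuts <- r2m(start_ts + cuts_min * 60)
  starts <- as.POSIXct(rep(NA, k), tz = lot_tz)
  stops <- as.POSIXct(rep(NA, k), tz = lot_tz)
  starts[1] <- start_ts
  for (j in 2:k) {
    seg <- as.numeric(difftime(if (j < k) cuts[j] else stop_ts, cuts[j - 1],
                               units = "mins"))
    gap <- stats::runif(1, 0, min(24 * 60, max(0, seg / 2)))
    starts[j] <- r2m(cuts[j - 1] + gap * 60)
  }
  stops[seq_len(k - 1)] <- cuts
  stops[k] <- stop_ts
  fast_tb(start_ts = starts, stop_ts = stops)
}

# Independent, scalar re-derivation of the expected pipeline result for
# the intended (non-noise) members of one course: effective stops with
# missing-stop substitution, indication resolution, admission linkage,
# CA/HA class, LOT, post-discharge split and first-match exclusion
# reason. This is what the pipeline must recover from the raw tables.
derive_truth_course <- function(members, adms, thresholds = lot_thresholds()) {
  ord <- order(members$start_ts, members$prescription_id)
  members <- members[ord, , drop = FALSE]
  eff <- members$stop_ts
  miss <- is.na(eff)
  eff[miss] <- date_as_ts(ts_date(members$start_ts[miss]))
  start_ts <- min(members$start_ts)
  stop_ts <- max(eff)
  max_miss <- suppressWarnings(max(as.numeric(eff[miss]), -Inf))
  max_real <- suppressWarnings(max(as.numeric(eff[!miss]), -Inf))
  truncated <- max_miss > max_real
  lot <- calendar_span_days(start_ts, stop_ts)

  lab <- members[!is.na(members$indication_kind), , drop = FALSE]
  if (nrow(lab) > 0) {
    first_kind <- lab$indication_kind[1]
    first_focus <- lab$indication_focus[1]
    first_spec <- lab$indication_specification[1]
    nlab <- nrow(lab)
    def_kind <- lab$indication_kind[nlab]
    def_focus <- lab$indication_focus[nlab]
    def_spec <- lab$indication_specification[nlab]
    at_max <- lab$start_ts == max(lab$start_ts)
    labels <- unique(indication_label(lab$indication_kind[at_max],
                                      lab$indication_focus[at_max],
                                      lab$indication_specification[at_max]))
    multi <- length(labels) > 1
    open_text <- any(lab$indication_kind == "open_text")
  } else {
    first_kind <- first_focus <- first_spec <- NA_character_
    def_kind <- def_focus <- def_spec <- NA_character_
    multi <- FALSE
    open_text <- TRUE
  }

  adms <- adms[order(adms$admit_ts), , drop = FALSE]
  inside <- adms$admit_ts <= start_ts & start_ts <= adms$discharge_ts
  pre_adm <- FALSE
  if (any(inside)) {
    link <- which(inside)[1]
  } else {
    over <- start_ts < adms$admit_ts & adms$admit_ts <= stop_ts
    link <- if (any(over)) which(over)[1] else NA_integer_
    pre_adm <- any(over)
  }
  if (!is.na(link)) {
    admit <- adms$admit_ts[link]
    discharge <- adms$discharge_ts[link]
    dur_h <- as.numeric(difftime(discharge, admit, units = "hours"))
    delta <- as.numeric(difftime(start_ts, admit, units = "hours"))
    acq <- if (delta < thresholds$ca_ha_boundary_hours) "CA" else "HA"
    pd <- min(lot, max(0L, as.integer(ts_date(stop_ts) - ts_date(discharge))))
    others <- adms[-link, , drop = FALSE]
  } else {
    dur_h <- NA_real_
    acq <- "unclassified"
    pd <- NA_integer_
    others <- adms
  }
  readmit <- nrow(others) > 0 && any(
    as.numeric(difftime(others$discharge_ts, others$admit_ts, units = "hours")) >=
      thresholds$min_admission_hours &
      others$admit_ts > start_ts & others$admit_ts < stop_ts)

  age <- if (!is.na(link)) adms$age_years[link] else NA_real_
  icu <- if (!is.na(link)) adms$icu_stay[link] else NA
  flags <- c(
    not_hospital_initiated = is.na(link),
    admission_under_12h = !is.na(dur_h) && dur_h < thresholds$min_admission_hours,
    pediatric = !is.na(age) && age < thresholds$pediatric_age,
    icu_during_admission = isTRUE(icu),
    multiple_final_diagnoses = multi,
    open_text_indication = open_text,
    duration_over_45d = lot > thresholds$max_course_days,
    readmitted_during_course = readmit
  )
  reason <- if (any(flags)) exclusion_reasons[which(flags)[1]] else NA_character_

  fast_tb(
    patient_id = members$patient_id[1],
    n_rx = nrow(members),
    prescription_ids = paste(members$prescription_id, collapse = ";"),
    start_ts = start_ts, stop_ts = stop_ts,
    truncated_missing_stop = truncated,
    first_kind = first_kind, first_focus = first_focus,
    first_specification = first_spec,
    definitive_kind = def_kind, definitive_focus = def_focus,
    definitive_specification = def_spec,
    lot_days = lot, acquisition = acq,
    post_discharge_days = pd,
    pre_admission = pre_adm,
    exclusion_reason = reason
  )
}

empty_rx_tibble <- function() {
  tibble(
    prescription_id = character(0), patient_id = character(0),
    drug_name = character(0), atc_code = character(0),
    dose_mg_per_day = numeric(0), route = character(0),
    start_ts = as.POSIXct(character(0), tz = lot_tz),
    stop_ts = as.POSIXct(character(0), tz = lot_tz),
    indication_kind = character(0), indication_focus = character(0),
    indication_specification = character(0),
    indication_free_text = character(0), setting = character(0)
  )
}

rx_row <- function(id, pid, drug, atc, dose, route, start, stop,
                   kind = NA_character_, focus = NA_character_,
                   spec = NA_character_, free = NA_character_,
                   setting = "inpatient") {
  fast_tb(prescription_id = id, patient_id = pid, drug_name = drug,
          atc_code = atc, dose_mg_per_day = dose, route = route,
          start_ts = start, stop_ts = stop, indication_kind = kind,
          indication_focus = focus, indication_specification = spec,
          indication_free_text = free, setting = setting)
}

gen_patient <- function(i, cfg, thresholds, catalog, lt_catalog) {
  pid <- sprintf("P%05d", i)
  ref <- cfg$reference
  rates <- cfg$rates

  excl_names <- c("open_text", "multi_final", "pediatric", "icu",
                  "short_admission", "readmission", "over_45d", "pre_admission")
  excl_p <- unlist(rates[excl_names])
  scenario <- sample(c("none", excl_names), 1,
                     prob = c(1 - sum(excl_p), excl_p))

  is_ca <- stats::runif(1) < cfg$cai_fraction
  if (scenario %in% c("short_admission", "pre_admission") && !is_ca) {
    scenario <- "none"
  }
  age <- if (scenario == "pediatric") sample(1:17, 1) else sample(18:95, 1)
  icu <- scenario == "icu"

  row_idx <- sample(nrow(ref), 1, prob = cfg$weights)
  ref_row <- ref[row_idx, ]
  lot <- draw_lot(ref_row, is_ca)
  if (scenario == "over_45d") lot <- sample(46:70, 1)
  if (scenario == "readmission") lot <- max(lot, 5L)
  if (scenario == "pre_admission") lot <- max(lot, 3L)

  admit <- r2m(as.POSIXct("2020-06-01 00:00", tz = lot_tz) +
                 sample(0:699, 1) * 86400 + stats::runif(1, 0, 24) * 3600)
  offset_h <- if (scenario == "short_admission") stats::runif(1, 0.5, 5)
  else if (scenario == "pre_admission") -stats::runif(1, 2, 12)
  else if (is_ca) stats::runif(1, 0.5, 47.5)
  else stats::runif(1, 48.5, 168)
  start_ts <- r2m(admit + offset_h * 3600)
  start_date <- ts_date(start_ts)
  stop_date <- start_date + lot - 1
  stop_ts <- if (lot == 1) {
    r2m(min(start_ts + stats::runif(1, 2, 6) * 3600, day_end(start_date)))
  } else {
    r2m(date_as_ts(stop_date) + stats::runif(1, 8, 22) * 3600)
  }

  pd_rate <- if (is_ca) cfg$post_discharge_rate_ca else cfg$post_discharge_rate_ha
  if (scenario == "short_admission") {
    discharge <- r2m(admit + 6 * 3600)
  } else if (scenario == "readmission") {
    discharge <- r2m(pmax(date_as_ts(stop_date - 2) + 12 * 3600,
                          start_ts + 3600, admit + 13 * 3600))
  } else if (lot >= 2 && stats::runif(1) < pd_rate) {
    pd_days <- sample(seq_len(lot - 1), 1)
    discharge <- r2m(pmax(date_as_ts(stop_date - pd_days) + 12 * 3600,
                          start_ts + 3600, admit + 13 * 3600))
  } else {
    discharge <- r2m(pmax(stop_ts + stats::runif(1, 2, 72) * 3600,
                          admit + 13 * 3600))
  }

  adms <- fast_tb(
    admission_id = paste0("A", pid), patient_id = pid,
    admit_ts = admit, discharge_ts = discharge,
    via_er = is_ca && stats::runif(1) < 0.6, icu_stay = icu,
    age_years = age,
    duration_hours = as.numeric(difftime(discharge, admit, units = "hours"))
  )
  if (scenario == "readmission") {
    admit2 <- r2m(discharge + 6 * 3600)
    adms <- dplyr::bind_rows(adms, fast_tb(
      admission_id = paste0("A", pid, "R"), patient_id = pid,
      admit_ts = admit2, discharge_ts = r2m(admit2 + 24 * 3600),
      via_er = FALSE, icu_stay = FALSE, age_years = age,
      duration_hours = 24
    ))
  }

  # intended course members
  k <- sample(1:4, 1)
  seg <- split_members(start_ts, stop_ts, k)
  k <- nrow(seg)
  drugs <- catalog[sample(nrow(catalog), k), ]
  kind <- sample(c("empirical", "targeted"), 1)
  lab_kind <- rep(kind, k)
  lab_focus <- rep(ref_row$focus, k)
  lab_spec <- rep(ref_row$specification, k)
  mid_unlab <- seq_len(k) > 1 & seq_len(k) < k & stats::runif(k) < 0.3
  lab_kind[mid_unlab] <- NA_character_
  lab_focus[mid_unlab] <- NA_character_
  lab_spec[mid_unlab] <- NA_character_
  setting <- ifelse(seg$start_ts > discharge, "outpatient", "inpatient")
  if (adms$via_er[1] &&
      as.numeric(difftime(seg$start_ts[1], admit, units = "hours")) < 4) {
    setting[1] <- "er"
  }
  members <- fast_tb(
    prescription_id = sprintf("%s-R%02d", pid, seq_len(k)),
    patient_id = pid, drug_name = drugs$drug_name, atc_code = drugs$atc_code,
    dose_mg_per_day = sample(c(1000, 1500, 2000, 3000), k, replace = TRUE),
    route = sample(c("intravenous", "oral"), k, replace = TRUE,
                   prob = c(0.7, 0.3)),
    start_ts = seg$start_ts, stop_ts = seg$stop_ts,
    indication_kind = lab_kind, indication_focus = lab_focus,
    indication_specification = lab_spec,
    indication_free_text = NA_character_, setting = setting
  )
  if (k >= 2 && cfg$working_diagnosis_rate > 0 &&
      ref_row$focus != "sepsis e.c.i." &&
      stats::runif(1) < cfg$working_diagnosis_rate) {
    members$indication_kind[1] <- "empirical"
    members$indication_focus[1] <- "sepsis e.c.i."
    members$indication_specification[1] <- NA_character_
  }
  if (scenario == "open_text") {
    members$indication_kind[k] <- "open_text"
    members$indication_focus[k] <- NA_character_
    members$indication_specification[k] <- NA_character_
    members$indication_free_text[k] <- "infection, see notes"
  }
  if (scenario == "multi_final") {
    alt <- ref[sample(setdiff(seq_len(nrow(ref)), row_idx), 1), ]
    extra_drug <- catalog[sample(nrow(catalog), 1), ]
    members <- dplyr::bind_rows(members, rx_row(
      sprintf("%s-R%02dX", pid, k), pid, extra_drug$drug_name,
      extra_drug$atc_code, 2000, "intravenous",
      members$start_ts[k], members$stop_ts[k],
      kind = "empirical", focus = alt$focus, spec = alt$specification))
  }
  noise_missing <- stats::runif(1) < rates$missing_stop
  if (noise_missing) {
    members$stop_ts[k] <- as.POSIXct(NA, tz = lot_tz)
  }

  # noise prescriptions the pipeline must remove or ignore
  noise <- empty_rx_tibble()
  noise_labels <- character(0)
  if (stats::runif(1) < rates$b1) {
    b1_start <- if (stats::runif(1) < 0.5) r2m(start_ts - stats::runif(1, 6, 20) * 3600)
    else r2m(start_ts + stats::runif(1, 0.2, 0.6) *
               as.numeric(difftime(stop_ts, start_ts, units = "secs")))
    noise <- dplyr::bind_rows(noise, rx_row(
      paste0(pid, "-NB1"), pid, "cefazolin", "J01DB04", 2000, "intravenous",
      b1_start, r2m(b1_start + sample(1:7, 1) * 86400), kind = "prophylaxis"))
    noise_labels <- c(noise_labels, "b1")
  }
  if (stats::runif(1) < rates$b2) {
    b2_start <- r2m(stop_ts + stats::runif(1, 1, 20) * 3600)
    if (stats::runif(1) < 0.4) {
      dur <- sample(15:40, 1)
      noise <- dplyr::bind_rows(noise, rx_row(
        paste0(pid, "-NB2"), pid, "trimethoprim/sulfamethoxazole", "J01EE01",
        480, "oral", b2_start,
        r2m(date_as_ts(ts_date(b2_start) + dur - 1) + 12 * 3600)))
    } else {
      lt <- lt_catalog[sample(nrow(lt_catalog), 1), ]
      dur <- sample(29:60, 1)
      noise <- dplyr::bind_rows(noise, rx_row(
        paste0(pid, "-NB2"), pid, lt$drug_name, lt$atc_code, 100, "oral",
        b2_start, r2m(date_as_ts(ts_date(b2_start) + dur - 1) + 12 * 3600)))
    }
    noise_labels <- c(noise_labels, "b2")
  }
  if (stats::runif(1) < rates$b3) {
    b3_start <- r2m(start_ts + stats::runif(1, 0.3, 0.7) *
                      as.numeric(difftime(stop_ts, start_ts, units = "secs")))
    noise <- dplyr::bind_rows(noise, rx_row(
      paste0(pid, "-NB3"), pid, "doxycycline", "J01AA02", 100, "oral",
      b3_start, r2m(b3_start + sample(10:30, 1) * 86400),
      kind = "prophylaxis"))
    noise_labels <- c(noise_labels, "b3")
  }
  if (stats::runif(1) < rates$non_j01) {
    nj_start <- r2m(admit + stats::runif(1, 0, 48) * 3600)
    noise <- dplyr::bind_rows(noise, rx_row(
      paste0(pid, "-NNJ"), pid, "paracetamol", "N02BE01", 3000, "oral",
      nj_start, r2m(nj_start + 5 * 86400)))
    noise_labels <- c(noise_labels, "non_j01")
  }
  if (noise_missing) noise_labels <- c(noise_labels, "missing_stop")

  truth <- derive_truth_course(members, adms, thresholds)
  noise_str <- paste(noise_labels, collapse = ";")
  noise_ids <- paste(noise$prescription_id, collapse = ";")
  truth <- dplyr::bind_cols(
    fast_tb(course_id = paste0(pid, "-1")), truth,
    fast_tb(scenario = scenario, noise = noise_str,
            noise_prescription_ids = noise_ids)
  )
  list(prescriptions = dplyr::bind_rows(members, noise),
       admissions = adms, truth = truth)
}

#' Generate a synthetic EHR extract with known ground truth
#'
#' Produces prescription and admission tables in the exact input schemas
#' of [read_prescriptions()] and [read_admissions()], together with a
#' ground-truth table stating, for each intended course, its member
#' prescriptions, first and definitive indications, start/stop, LOT,
#' acquisition class, post-discharge days and expected exclusion reason.
#' The ground truth is derived by an independent scalar application of
#' the surveillance rules to the intended members, so running the
#' pipeline on the (noise-laden) raw tables and comparing against the
#' ground truth exercises every processing stage end to end.
#'
#' @param config a [simulation_config()]
#' @param thresholds a [lot_thresholds()] object the truth derivation
#'   assumes
#' @return list with `prescriptions`, `admissions`, `ground_truth`
#' @export
#' @examples
#' sim <- generate_ehr(simulation_config(n_patients = 20, seed = 7))
#' nrow(sim$ground_truth)
generate_ehr <- function(config = simulation_config(),
                         thresholds = lot_thresholds()) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(config$seed, {
    catalog <- drug_catalog()
    lt_catalog <- long_term_catalog()
    pats <- lapply(seq_len(config$n_patients), gen_patient,
                   cfg = config, thresholds = thresholds,
                   catalog = catalog, lt_catalog = lt_catalog)
    rx <- dplyr::bind_rows(lapply(pats, `[[`, "prescriptions"))
    adms <- dplyr::bind_rows(lapply(pats, `[[`, "admissions"))
    truth <- dplyr::bind_rows(lapply(pats, `[[`, "truth"))
    # shuffle prescription rows so nothing downstream can rely on input order
    rx <- rx[sample(nrow(rx)), , drop = FALSE]
    list(prescriptions = rx, admissions = adms, ground_truth = truth)
  })
}

#' Inject a named complexity scenario into generated tables
#'
#' Adds the scenario's prescriptions/admissions around an existing
#' ground-truth course and updates the ground truth so the correct
#' pipeline behaviour is known: `B1` and `B3` add a prophylaxis-labelled
#' prescription (overlapping the course start or mid-course) that must
#' be removed; `B2` adds a trailing unlabelled long-duration
#' prescription of a drug covered by the presumed-prophylaxis rules;
#' `B2_unlisted` adds the same pattern with a drug outside the rule set —
#' a documented fidelity limit: the pipeline will extend the course, so
#' recovery of this course is expected to fail; `missing_stop` removes
#' the last member's stop date (expected truncation at its start date);
#' `readmission` adds a qualifying admission inside the course;
#' `over_45d` extends the course past 45 days.
#'
#' @param tables list from [generate_ehr()]
#' @param scenario one of `"B1"`, `"B2"`, `"B2_unlisted"`, `"B3"`,
#'   `"missing_stop"`, `"readmission"`, `"over_45d"`
#' @param course_id ground-truth course to target
#' @param thresholds a [lot_thresholds()] object
#' @return modified `tables`
#' @export
inject_scenario <- function(tables, scenario, course_id,
                            thresholds = lot_thresholds()) {
  gt <- tables$ground_truth
  idx <- which(gt$course_id == course_id)
  if (length(idx) != 1) abort(sprintf("unknown ground-truth course: %s", course_id))
  row <- gt[idx, ]
  pid <- row$patient_id
  member_ids <- strsplit(row$prescription_ids, ";", fixed = TRUE)[[1]]
  inj_id <- paste0(course_id, "-INJ", scenario)

  add_noise <- function(rx_new, label) {
    tables$prescriptions <- dplyr::bind_rows(tables$prescriptions, rx_new)
    gt$noise[idx] <- paste(c(strsplit(row$noise, ";")[[1]], label),
                           collapse = ";")
    gt$noise_prescription_ids[idx] <- paste(
      c(strsplit(row$noise_prescription_ids, ";")[[1]], rx_new$prescription_id),
      collapse = ";")
    tables$ground_truth <- gt
    tables
  }
  recompute <- function(tables) {
    members <- tables$prescriptions[
      tables$prescriptions$prescription_id %in% member_ids, , drop = FALSE]
    adms <- tables$admissions[tables$admissions$patient_id == pid, , drop = FALSE]
    new_truth <- derive_truth_course(members, adms, thresholds)
    keep <- c("course_id", "scenario", "noise", "noise_prescription_ids")
    tables$ground_truth[idx, setdiff(names(gt), keep)] <-
      new_truth[setdiff(names(gt), keep)]
    tables
  }

  if (scenario == "B1") {
    start <- r2m(row$start_ts - 12 * 3600)
    return(add_noise(rx_row(inj_id, pid, "cefazolin", "J01DB04", 2000,
                            "intravenous", start, r2m(start + 2 * 86400),
                            kind = "prophylaxis"), "B1"))
  }
  if (scenario == "B2") {
    start <- r2m(row$stop_ts + 6 * 3600)
    return(add_noise(rx_row(inj_id, pid, "nitrofurantoin", "J01XE01", 100,
                            "oral", start,
                            r2m(date_as_ts(ts_date(start) + 34) + 12 * 3600)),
                     "B2"))
  }
  if (scenario == "B2_unlisted") {
    start <- r2m(row$stop_ts + 6 * 3600)
    return(add_noise(rx_row(inj_id, pid, "amoxicillin", "J01CA04", 1500,
                            "oral", start,
                            r2m(date_as_ts(ts_date(start) + 34) + 12 * 3600)),
                     "B2_unlisted"))
  }
  if (scenario == "B3") {
    start <- r2m(row$start_ts +
                   as.numeric(difftime(row$stop_ts, row$start_ts, units = "secs")) / 2)
    return(add_noise(rx_row(inj_id, pid, "doxycycline", "J01AA02", 100, "oral",
                            start, r2m(start + 30 * 86400),
                            kind = "prophylaxis"), "B3"))
  }
  if (scenario == "missing_stop") {
    members <- tables$prescriptions[
      tables$prescriptions$prescription_id %in% member_ids, , drop = FALSE]
    last_id <- members$prescription_id[
      order(members$start_ts, members$prescription_id)][nrow(members)]
    tables$prescriptions$stop_ts[
      tables$prescriptions$prescription_id == last_id] <- as.POSIXct(NA, tz = lot_tz)
    tables$ground_truth$noise[idx] <-
      paste(c(strsplit(row$noise, ";")[[1]], "missing_stop"), collapse = ";")
    return(recompute(tables))
  }
  if (scenario == "readmission") {
    adm <- tables$admissions[tables$admissions$patient_id == pid &
                               tables$admissions$admission_id == paste0("A", pid), ]
    admit2 <- r2m(adm$discharge_ts + 6 * 3600)
    if (admit2 >= row$stop_ts) {
      abort("readmission scenario needs a course extending well past discharge")
    }
    tables$admissions <- dplyr::bind_rows(tables$admissions, tibble(
      admission_id = paste0("A", pid, "-INJ"), patient_id = pid,
      admit_ts = admit2, discharge_ts = r2m(admit2 + 24 * 3600),
      via_er = FALSE, icu_stay = FALSE, age_years = adm$age_years,
      duration_hours = 24))
    return(recompute(tables))
  }
  if (scenario == "over_45d") {
    members <- tables$prescriptions[
      tables$prescriptions$prescription_id %in% member_ids, , drop = FALSE]
    last_id <- members$prescription_id[
      order(members$start_ts, members$prescription_id)][nrow(members)]
    new_stop <- r2m(date_as_ts(ts_date(row$start_ts) + 49) + 12 * 3600)
    tables$prescriptions$stop_ts[
      tables$prescriptions$prescription_id == last_id] <- new_stop
    return(recompute(tables))
  }
  abort(sprintf("unknown scenario: %s", scenario))
}

#' Compare pipeline output against generated ground truth
#'
#' Joins each ground-truth course to the corresponding assembled course
#' and checks, field by field, whether the pipeline recovered the
#' intended result: course boundaries and membership, definitive
#' indication, acquisition class, LOT, post-discharge days, truncation
#' flag and exclusion reason. A truth course with no pipeline
#' counterpart fails all checks.
#'
#' @param ground_truth ground-truth tibble from [generate_ehr()]
#' @param courses annotated course tibble (`$courses` from
#'   [build_courses()])
#' @return tibble with one row per ground-truth course and logical
#'   `*_match` columns plus `all_match`
#' @export
compare_to_truth <- function(ground_truth, courses) {
  same <- function(a, b) {
    (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  }
  j <- dplyr::left_join(
    ground_truth, courses, by = c("course_id", "patient_id"),
    suffix = c(".truth", ".obs"))
  found <- j$course_id %in% courses$course_id
  out <- tibble(
    course_id = j$course_id,
    boundaries_match = found &
      same(j$start_ts.truth, j$start_ts.obs) &
      same(j$stop_ts.truth, j$stop_ts.obs) &
      same(j$prescription_ids.truth, j$prescription_ids.obs),
    indication_match = found &
      same(j$definitive_kind.truth, j$definitive_kind.obs) &
      same(j$definitive_focus.truth, j$definitive_focus.obs) &
      same(j$definitive_specification.truth, j$definitive_specification.obs),
    acquisition_match = found & same(j$acquisition.truth, j$acquisition.obs),
    lot_match = found & same(j$lot_days.truth, j$lot_days.obs),
    post_discharge_match = found &
      same(j$post_discharge_days.truth, j$post_discharge_days.obs),
    truncation_match = found &
      same(j$truncated_missing_stop.truth, j$truncated_missing_stop.obs),
    exclusion_match = found &
      same(j$exclusion_reason.truth, j$exclusion_reason.obs)
  )
  out$all_match <- out$boundaries_match & out$indication_match &
    out$acquisition_match & out$lot_match & out$post_discharge_match &
    out$truncation_match & out$exclusion_match
  out
}
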