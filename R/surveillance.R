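indication_group <- function(focus, specification) {
  dplyr::case_when(
    is.na(focus) ~ "unspecified",
    is.na(specification) ~ focus,
    TRUE ~ paste0(focus, "-", specification)
  )
}

#' Surveillance summary per indication and acquisition class
#'
#' For each (definitive indication, acquisition) cell: the number of
#' courses, the share of that acquisition class, the median LOT with
#' interquartile range (linear interpolation between order statistics),
#' the share of courses with any post-discharge treatment, and — among
#' those — the mean percentage of the LOT given post-discharge. An
#' `overall` attribute holds the same quantities per acquisition class
#' and in total.
#'
#' @param courses included course tibble (after [build_courses()])
#' @return summary tibble; per-acquisition totals in `attr(, "overall")`
#' @export
summarize_courses <- function(courses) {
  if (nrow(courses) == 0) {
    out <- tibble(indication = character(0), acquisition = character(0),
                  n = integer(0), pct_of_acquisition = numeric(0),
                  lot_median = numeric(0), lot_q1 = numeric(0),
                  lot_q3 = numeric(0), pct_with_post_discharge = numeric(0),
                  mean_pct_of_lot_post_discharge = numeric(0))
    attr(out, "overall") <- out[0, -1]
    return(out)
  }
  df <- courses %>%
    dplyr::mutate(indication = indication_group(.data$definitive_focus,
                                                .data$definitive_specification))
  cell_stats <- function(d) {
    pd <- d$post_discharge_days
    with_pd <- !is.na(pd) & pd > 0
    tibble(
      n = nrow(d),
      lot_median = stats::median(d$lot_days),
      lot_q1 = unname(stats::quantile(d$lot_days, 0.25, type = 7)),
      lot_q3 = unname(stats::quantile(d$lot_days, 0.75, type = 7)),
      pct_with_post_discharge = 100 * mean(with_pd),
      mean_pct_of_lot_post_discharge =
        if (any(with_pd)) mean(d$post_discharge_pct[with_pd]) else NA_real_
    )
  }
  out <- df %>%
    dplyr::group_by(.data$indication, .data$acquisition) %>%
    dplyr::group_modify(~ cell_stats(.x)) %>%
    dplyr::ungroup() %>%
    dplyr::group_by(.data$acquisition) %>%
    dplyr::mutate(pct_of_acquisition = round_half_up(100 * n / sum(n), 1)) %>%
    dplyr::ungroup() %>%
    dplyr::select("indication", "acquisition", "n", "pct_of_acquisition",
                  "lot_median", "lot_q1", "lot_q3",
                  "pct_with_post_discharge", "mean_pct_of_lot_post_discharge") %>%
    dplyr::arrange(.data$indication, .data$acquisition)
  overall <- dplyr::bind_rows(
    df %>% dplyr::group_by(acquisition = .data$acquisition) %>%
      dplyr::group_modify(~ cell_stats(.x)) %>% dplyr::ungroup(),
    dplyr::bind_cols(tibble(acquisition = "total"), cell_stats(df))
  )
  attr(out, "overall") <- overall
  out
}

#' Stratified validation sampling plan
#'
#' Courses are sampled for manual chart review in five disjoint strata:
#' urinary tract infections, respiratory tract infections and
#' intra-abdominal infections at 5% each, all remaining diagnoses at
#' 5%, and — because prescriptions that are incorrectly never stopped
#' concentrate there — courses of extended duration (over 45 days) at
#' 20%. The extended stratum takes precedence over the diagnosis strata.
#'
#' @param uti,rti,iai,other,extended per-stratum sampling fractions
#' @return a list of class `sampling_plan`
#' @export
sampling_plan <- function(uti = 0.05, rti = 0.05, iai = 0.05,
                          other = 0.05, extended = 0.20) {
  fr <- c(UTI = uti, RTI = rti, IAI = iai, other = other, extended = extended)
  stopifnot(all(fr > 0), all(fr <= 1))
  structure(list(fractions = fr), class = "sampling_plan")
}

assign_stratum <- function(courses, max_course_days = 45) {
  dplyr::case_when(
    courses$lot_days > max_course_days ~ "extended",
    !is.na(courses$definitive_focus) & courses$definitive_focus == "UTI" ~ "UTI",
    !is.na(courses$definitive_focus) & courses$definitive_focus == "RTI" ~ "RTI",
    !is.na(courses$definitive_focus) &
      courses$definitive_focus == "intra-abdominal" ~ "IAI",
    TRUE ~ "other"
  )
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Draw the stratified validation sample
#'
#' Simple random sampling without replacement within each stratum, with
#' sample sizes `round(fraction * stratum size)` (half-up, minimum 1 for
#' a non-empty stratum). The draw is seeded and reproducible. The sample
#' is intended to be drawn before the over-45-days exclusion is applied,
#' so extended-duration courses can be reviewed.
#'
#' @param courses course tibble carrying definitive indications and
#'   `lot_days`
#' @param plan a [sampling_plan()]
#' @param seed integer seed for the draw
#' @param max_course_days boundary defining the extended stratum
#' @return tibble (`course_id`, `stratum`) of sampled courses
#' @export
draw_validation_sample <- function(courses, plan = sampling_plan(), seed = 1L,
                                   max_course_days = 45) {
  stratum <- assign_stratum(courses, max_course_days)
  with_local_seed(seed, {
    picked <- lapply(names(plan$fractions), function(s) {
      ids <- courses$course_id[stratum == s]
      if (length(ids) == 0) {
        inform(sprintf("validation sample: stratum %s is empty", s))
        return(character(0))
      }
      k <- max(1L, as.integer(round_half_up(plan$fractions[[s]] * length(ids), 0)))
      sort(sample(ids, k))
    })
    tibble(
      course_id = unlist(picked),
      stratum = rep(names(plan$fractions), lengths(picked))
    )
  })
}

error_rate_row <- function(d, label) {
  n <- nrow(d)
  tibble(
    category = label,
    n_validated = n,
    n_indication_incorrect = sum(!d$indication_correct),
    indication_error_pct = round_half_up(100 * sum(!d$indication_correct) / n, 1),
    n_indication_site_incorrect = sum(!d$indication_correct_site),
    indication_site_error_pct =
      round_half_up(100 * sum(!d$indication_correct_site) / n, 1),
    n_lot_rx_incorrect = sum(!d$lot_matches_prescriptions),
    lot_rx_error_pct =
      round_half_up(100 * sum(!d$lot_matches_prescriptions) / n, 1),
    n_lot_notes_incorrect = sum(!d$lot_matches_notes),
    lot_notes_error_pct = round_half_up(100 * sum(!d$lot_matches_notes) / n, 1)
  )
}

#' Error rates of the validated sample
#'
#' The error rate is the number of incorrectly retrieved indications (or
#' incorrectly calculated LOT) divided by the number of validated
#' courses, reported per infection category (intra-abdominal, RTI, UTI,
#' other), pooled, and split by acquisition class. The site-level
#' indication rate forgives errors in the UTI/RTI sub-type, comparing
#' only the site of infection. Percentages are rounded half-up to one
#' decimal.
#'
#' @param validation reviewer verdicts (see [read_validation()])
#' @param courses course tibble supplying each course's definitive focus
#'   and acquisition class
#' @return tibble with one row per category plus `total`, `CA` and `HA`
#' @export
compute_error_rates <- function(validation, courses) {
  unknown <- setdiff(validation$course_id, courses$course_id)
  if (length(unknown) > 0) {
    abort(sprintf("validation records reference unknown course id(s): %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  joined <- dplyr::left_join(
    validation,
    courses[c("course_id", "definitive_focus", "acquisition")],
    by = "course_id")
  category <- dplyr::case_when(
    !is.na(joined$definitive_focus) &
      joined$definitive_focus == "intra-abdominal" ~ "IAI",
    !is.na(joined$definitive_focus) & joined$definitive_focus == "RTI" ~ "RTI",
    !is.na(joined$definitive_focus) & joined$definitive_focus == "UTI" ~ "UTI",
    TRUE ~ "other"
  )
  rows <- lapply(c("IAI", "RTI", "UTI", "other"), function(cat) {
    d <- joined[category == cat, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    error_rate_row(d, cat)
  })
  acq_rows <- lapply(c("CA", "HA"), function(a) {
    d <- joined[!is.na(joined$acquisition) & joined$acquisition == a, ,
                drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    error_rate_row(d, a)
  })
  dplyr::bind_rows(c(rows, list(error_rate_row(joined, "total")), acq_rows))
}

#' Tabulate causes of LOT-versus-notes mismatches
#'
#' Among validated courses whose computed LOT disagreed with the
#' clinical notes, counts the identified causes (hospital transfer,
#' treatment already started before admission, antibiotics mislabelled
#' as prophylaxis, outpatient parenteral therapy, single-dose
#' prescribing) with their share of the mismatched subset; records
#' without a recorded cause are bucketed as `other`.
#'
#' @param validation reviewer verdicts
#' @return tibble (`cause`, `n`, `pct`), empty when nothing mismatched
#' @export
tabulate_error_causes <- function(validation) {
  mism <- validation[!validation$lot_matches_notes, , drop = FALSE]
  if (nrow(mism) == 0) {
    return(tibble(cause = character(0), n = integer(0), pct = numeric(0)))
  }
  cause <- ifelse(is.na(mism$error_cause), "other", mism$error_cause)
  tab <- table(factor(cause, levels = error_causes))
  tibble(
    cause = names(tab),
    n = as.integer(tab),
    pct = round_half_up(100 * as.integer(tab) / nrow(mism), 1)
  ) %>% dplyr::filter(.data$n > 0 | .data$cause != "other")
}
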