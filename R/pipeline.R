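#' Run the full course-building pipeline
#'
#' Chains the processing stages that turn raw EHR extracts into analysis-
#' ready treatment courses: therapeutic filtering (ATC J01, labelled and
#' presumed prophylaxis removed), assembly by the 24-hour gap rule,
#' indication resolution, admission linkage, CA/HA classification at the
#' 48-hour boundary, LOT and post-discharge measurement, and the
#' exclusion cascade with conserved counts.
#'
#' @param prescriptions prescriptions tibble (see [read_prescriptions()])
#' @param admissions admissions tibble (see [read_admissions()])
#' @param thresholds a [lot_thresholds()] object
#' @param rules a [prophylaxis_rules()] object
#' @param quiet suppress per-stage count messages
#' @return list with `courses` (all assembled courses, annotated),
#'   `included`, `excluded`, `flow` (exclusion flow with conserved
#'   counts), `removals` (prescription-level filter counts) and
#'   `members` (prescriptions annotated with their course id)
#' @export
#' @examples
#' res <- build_courses(example_prescriptions(), example_admissions(),
#'                      quiet = TRUE)
#' res$flow
build_courses <- function(prescriptions, admissions,
                          thresholds = lot_thresholds(),
                          rules = prophylaxis_rules(), quiet = FALSE) {
  therapeutic <- filter_therapeutic(prescriptions, rules, quiet = quiet)
  courses <- assemble_courses(therapeutic, gap_hours = thresholds$gap_hours,
                              quiet = quiet)
  members <- attr(courses, "members")
  attr(courses, "members") <- NULL
  courses <- attach_admissions(courses, admissions)
  courses <- classify_acquisition(courses, thresholds)
  courses <- compute_lot(courses)
  courses <- compute_post_discharge(courses)
  res <- apply_exclusions(courses, admissions, thresholds, quiet = quiet)
  list(courses = res$courses, included = res$included,
       excluded = res$excluded, flow = res$flow,
       removals = attr(therapeutic, "removals"), members = members)
}

#' Load thresholds, prophylaxis rules and sampling plan from YAML
#'
#' The configuration file may carry any of the blocks `thresholds`,
#' `prophylaxis` and `sampling`, each overriding the corresponding
#' defaults; absent entries keep their default values.
#'
#' @param path YAML file path, or `NULL` for all defaults
#' @return list with `thresholds`, `rules`, `plan`
#' @export
load_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  thr <- do.call(lot_thresholds, cfg$thresholds %||% list())
  rules <- do.call(prophylaxis_rules, cfg$prophylaxis %||% list())
  plan <- do.call(sampling_plan, cfg$sampling %||% list())
  list(thresholds = thr, rules = rules, plan = plan)
}
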