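test_that("presumed-prophylaxis rules reproduce every duration/dose boundary", {
  rules <- prophylaxis_rules()
  # rx_days builds a prescription whose inclusive calendar span is `days`
  rx_days <- function(drug, days, dose = 100) {
    start <- as.Date("2020-06-01")
    mk_rx("R1", "2020-06-01T10:00",
          paste0(format(start + days - 1), "T10:00"),
          drug = drug, dose = dose)
  }
  expect_true(is_presumed_prophylaxis(rx_days("nitrofurantoin", 30), rules))
  expect_false(is_presumed_prophylaxis(rx_days("nitrofurantoin", 28), rules))
  expect_true(is_presumed_prophylaxis(rx_days("nitrofurantoin", 29), rules))
  expect_true(is_presumed_prophylaxis(
    rx_days("trimethoprim/sulfamethoxazole", 15, dose = 480), rules))
  expect_false(is_presumed_prophylaxis(
    rx_days("trimethoprim/sulfamethoxazole", 14, dose = 480), rules))
  expect_false(is_presumed_prophylaxis(
    rx_days("trimethoprim/sulfamethoxazole", 50, dose = 960), rules))
  expect_true(is_presumed_prophylaxis(
    rx_days("trimethoprim/sulfamethoxazole", 51, dose = 960), rules))
  expect_false(is_presumed_prophylaxis(rx_days("amoxicillin", 40), rules))
  # no stop date: duration unknown, never presumed prophylaxis
  expect_false(is_presumed_prophylaxis(
    mk_rx("R1", "2020-06-01T10:00", drug = "nitrofurantoin"), rules))
})

test_that("therapeutic filter removes non-J01, labelled and presumed prophylaxis", {
  rx <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T10:00", "2020-06-05T10:00",
          kind = "empirical", focus = "UTI", spec = "cystitis"),
    mk_rx("R2", "2020-06-01T09:00", "2020-06-06T10:00",
          drug = "paracetamol", atc = "N02BE01"),
    mk_rx("R3", "2020-06-01T08:00", "2020-06-02T08:00",
          drug = "cefazolin", atc = "J01DB04", kind = "prophylaxis"),
    mk_rx("R4", "2020-06-05T12:00", "2020-07-20T12:00",
          drug = "nitrofurantoin", atc = "J01XE01")
  )
  kept <- filter_therapeutic(rx, quiet = TRUE)
  expect_identical(kept$prescription_id, "R1")
  removals <- attr(kept, "removals")
  expect_identical(sum(removals$n) + nrow(kept), nrow(rx))
  expect_identical(removals$n, c(1L, 1L, 1L))

  empty <- filter_therapeutic(rx[0, ], quiet = TRUE)
  expect_identical(nrow(empty), 0L)
})

test_that("gap rule links within 24 h inclusive and splits beyond", {
  # 22 h gap -> one course
  rx <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-05T12:00"),
    mk_rx("R2", "2020-06-06T10:00", "2020-06-08T10:00")
  )
  expect_identical(nrow(assemble_courses(rx, quiet = TRUE)), 1L)

  # exactly 24 h still links; one minute more splits
  rx24 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-05T12:00"),
    mk_rx("R2", "2020-06-06T12:00", "2020-06-08T10:00")
  )
  expect_identical(nrow(assemble_courses(rx24, quiet = TRUE)), 1L)
  rx25 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-05T12:00"),
    mk_rx("R2", "2020-06-06T12:01", "2020-06-08T10:00")
  )
  expect_identical(nrow(assemble_courses(rx25, quiet = TRUE)), 2L)

  # gaps 10 h then 30 h -> {R1,R2},{R3}
  rx3 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-02T08:00"),
    mk_rx("R2", "2020-06-02T18:00", "2020-06-04T08:00"),
    mk_rx("R3", "2020-06-05T14:00", "2020-06-07T08:00")
  )
  courses <- assemble_courses(rx3, quiet = TRUE)
  expect_identical(nrow(courses), 2L)
  expect_setequal(courses$prescription_ids, c("R1;R2", "R3"))

  # single prescription: identical start/stop
  one <- assemble_courses(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-04T10:00"), quiet = TRUE)
  expect_identical(one$start_ts, pt("2020-06-01T08:00"))
  expect_identical(one$stop_ts, pt("2020-06-04T10:00"))
})

test_that("missing stop dates truncate the course at the last start date", {
  rx <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-04T10:00"),
    mk_rx("R2", "2020-06-05T09:00")
  )
  course <- assemble_courses(rx, quiet = TRUE)
  expect_identical(nrow(course), 1L)
  expect_identical(course$stop_ts, pt("2020-06-05T00:00"))
  expect_true(course$truncated_missing_stop)
  expect_identical(compute_lot(course)$lot_days, 5L)

  # mid-course missing stop: gap evaluated from the substituted stop;
  # a later real stop defines the course end without truncation
  rx2 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00"),
    mk_rx("R2", "2020-06-01T20:00", "2020-06-06T10:00")
  )
  course2 <- assemble_courses(rx2, quiet = TRUE)
  expect_identical(nrow(course2), 1L)
  expect_identical(course2$stop_ts, pt("2020-06-06T10:00"))
  expect_false(course2$truncated_missing_stop)

  # substituted stop at start-of-day: a follow-up more than 24 h past
  # that midnight opens a new course even if close to the nominal start
  rx3 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T23:00"),
    mk_rx("R2", "2020-06-03T01:00", "2020-06-05T10:00")
  )
  expect_identical(nrow(assemble_courses(rx3, quiet = TRUE)), 2L)
})

test_that("first and definitive indications resolve; flags raised", {
  rx <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-03T10:00",
          kind = "empirical", focus = "sepsis e.c.i."),
    mk_rx("R2", "2020-06-04T09:00", "2020-06-08T10:00",
          kind = "targeted", focus = "UTI", spec = "complicated")
  )
  course <- assemble_courses(rx, quiet = TRUE)
  expect_identical(course$first_focus, "sepsis e.c.i.")
  expect_identical(course$definitive_focus, "UTI")
  expect_identical(course$definitive_specification, "complicated")
  expect_false(course$multiple_final_diagnoses)

  # single member: first = definitive
  one <- assemble_courses(rx[1, ], quiet = TRUE)
  expect_identical(one$first_focus, one$definitive_focus)

  # two distinct labels at the same (latest) start time
  rx2 <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-05T10:00",
          kind = "empirical", focus = "UTI", spec = "cystitis"),
    mk_rx("R2", "2020-06-01T08:00", "2020-06-05T10:00",
          kind = "empirical", focus = "intra-abdominal")
  )
  expect_true(assemble_courses(rx2, quiet = TRUE)$multiple_final_diagnoses)

  # open-text member flags the course; unlabeled course treated the same
  rx3 <- mk_rx("R1", "2020-06-01T08:00", "2020-06-03T10:00",
               kind = "open_text", free = "fever, not sure")
  expect_true(assemble_courses(rx3, quiet = TRUE)$open_text_indication)
  rx4 <- mk_rx("R1", "2020-06-01T08:00", "2020-06-03T10:00")
  c4 <- assemble_courses(rx4, quiet = TRUE)
  expect_true(c4$unlabeled)
  expect_true(c4$open_text_indication)
})

test_that("greedy assembly equals interval-graph connected components", {
  set.seed(4711)
  n_instances <- 1000
  for (i in seq_len(n_instances)) {
    n <- sample(1:15, 1)
    start <- pt("2020-06-01T00:00") + runif(n, 0, 30 * 86400)
    start <- as.POSIXct(floor(as.numeric(start) / 60) * 60,
                        origin = "1970-01-01", tz = "UTC")
    dur <- runif(n, 0, 10 * 86400)
    stop <- as.POSIXct(floor(as.numeric(start + dur) / 60) * 60,
                       origin = "1970-01-01", tz = "UTC")
    stop[runif(n) < 0.2] <- NA
    rx <- tibble::tibble(
      prescription_id = sprintf("R%02d", seq_len(n)), patient_id = "P1",
      drug_name = "ceftriaxone", atc_code = "J01DD04",
      dose_mg_per_day = 2000, route = "intravenous",
      start_ts = start, stop_ts = stop,
      indication_kind = NA_character_, indication_focus = NA_character_,
      indication_specification = NA_character_,
      indication_free_text = NA_character_, setting = "inpatient"
    )
    greedy <- course_partition(assemble_courses(rx, quiet = TRUE))
    oracle <- oracle_components(rx)
    if (!same_partition(greedy, oracle)) {
      fail(sprintf("partition mismatch at instance %d", i))
      break
    }
  }
  succeed()
})

test_that("assembly conserves prescriptions, is idempotent and monotone in the gap", {
  sim <- default_cohort()
  therapeutic <- filter_therapeutic(sim$prescriptions, quiet = TRUE)
  courses <- assemble_courses(therapeutic, quiet = TRUE)
  members <- attr(courses, "members")
  # partition: every therapeutic prescription in exactly one course
  expect_identical(nrow(members), nrow(therapeutic))
  expect_identical(sort(members$prescription_id),
                   sort(therapeutic$prescription_id))
  ids <- unlist(strsplit(courses$prescription_ids, ";", fixed = TRUE))
  expect_identical(sort(ids), sort(therapeutic$prescription_id))

  # idempotence: re-assembling the members reproduces identical boundaries
  again <- assemble_courses(
    members[setdiff(names(members), "course_id")], quiet = TRUE)
  expect_same_courses <- function(a, b) {
    a <- dplyr::arrange(a, patient_id, start_ts)
    b <- dplyr::arrange(b, patient_id, start_ts)
    expect_identical(a$prescription_ids, b$prescription_ids)
    expect_identical(a$start_ts, b$start_ts)
    expect_identical(a$stop_ts, b$stop_ts)
  }
  expect_same_courses(courses, again)

  # monotonicity: shrinking the gap never merges previously separate courses
  narrow <- assemble_courses(therapeutic, gap_hours = 6, quiet = TRUE)
  expect_gte(nrow(narrow), nrow(courses))
  wide_of <- attr(courses, "members")
  narrow_of <- attr(narrow, "members")
  key <- dplyr::left_join(
    narrow_of[c("prescription_id", "course_id")],
    wide_of[c("prescription_id", "course_id")],
    by = "prescription_id", suffix = c(".narrow", ".wide"))
  refinement <- dplyr::n_distinct(
    key[c("course_id.narrow", "course_id.wide")]) ==
    dplyr::n_distinct(key$course_id.narrow)
  expect_true(refinement)
})
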