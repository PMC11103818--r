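mk_course <- function(start, stop, pid = "P1", id = "P1-1",
                      focus = "UTI", spec = "cystitis") {
  rx <- mk_rx("R1", start, stop, pid = pid, kind = "empirical",
              focus = focus, spec = spec)
  courses <- assemble_courses(rx, quiet = TRUE)
  courses$course_id <- id
  courses
}

test_that("courses link to the admission containing their start", {
  adms <- mk_adm("A1", "2020-06-01T06:00", "2020-06-06T10:00")
  # 6 h into a 5-day admission -> linked
  c1 <- attach_admissions(mk_course("2020-06-01T12:00", "2020-06-04T10:00"), adms)
  expect_identical(c1$admission_id, "A1")
  expect_false(c1$not_hospital_initiated)

  # started two days after discharge, no other admission -> not hospital initiated
  c2 <- attach_admissions(mk_course("2020-06-08T12:00", "2020-06-12T10:00"), adms)
  expect_true(c2$not_hospital_initiated)
  expect_identical(classify_acquisition(c2)$acquisition, "unclassified")

  # started during an ER visit that opened the admission -> linked
  er <- mk_adm("A2", "2020-06-01T06:00", "2020-06-06T10:00", via_er = TRUE)
  c3 <- attach_admissions(mk_course("2020-06-01T06:30", "2020-06-04T10:00"), er)
  expect_identical(c3$admission_id, "A2")

  # started before admission but continuing into it -> linked, flagged
  c4 <- attach_admissions(mk_course("2020-05-31T20:00", "2020-06-04T10:00"), adms)
  expect_identical(c4$admission_id, "A1")
  expect_true(c4$pre_admission)
  expect_identical(classify_acquisition(c4)$acquisition, "CA")

  # overlapping admission windows are a data-integrity error
  bad <- dplyr::bind_rows(
    mk_adm("A1", "2020-06-01T06:00", "2020-06-06T10:00"),
    mk_adm("A3", "2020-06-05T06:00", "2020-06-09T10:00"))
  expect_error(attach_admissions(mk_course("2020-06-01T12:00",
                                           "2020-06-04T10:00"), bad),
               "overlapping")
})

test_that("CA/HA classification respects the 48 h boundary with HA on the tie", {
  adms <- mk_adm("A1", "2020-06-01T00:00", "2020-06-20T10:00")
  classify <- function(start, stop) {
    classify_acquisition(attach_admissions(mk_course(start, stop), adms))
  }
  expect_identical(classify("2020-06-01T20:00", "2020-06-05T10:00")$acquisition, "CA")
  expect_identical(classify("2020-06-03T12:00", "2020-06-07T10:00")$acquisition, "HA")
  expect_identical(classify("2020-06-03T00:00", "2020-06-07T10:00")$acquisition, "HA")
  expect_identical(classify("2020-06-02T23:59", "2020-06-07T10:00")$acquisition, "CA")
})

test_that("LOT counts inclusive calendar days irrespective of agents", {
  c1 <- compute_lot(mk_course("2020-06-01T22:00", "2020-06-03T08:00"))
  expect_identical(c1$lot_days, 3L)
  c2 <- compute_lot(mk_course("2020-06-01T08:00", "2020-06-01T20:00"))
  expect_identical(c2$lot_days, 1L)
  # two overlapping agents covering 06-01..06-04: each day counted once
  rx <- dplyr::bind_rows(
    mk_rx("R1", "2020-06-01T08:00", "2020-06-03T10:00"),
    mk_rx("R2", "2020-06-02T08:00", "2020-06-04T12:00", drug = "ciprofloxacin",
          atc = "J01MA02")
  )
  c3 <- compute_lot(assemble_courses(rx, quiet = TRUE))
  expect_identical(c3$lot_days, 4L)
})

test_that("post-discharge days count course days strictly after discharge", {
  adms <- mk_adm("A1", "2020-06-01T00:00", "2020-06-05T14:00")
  prep <- function(start, stop) {
    compute_post_discharge(compute_lot(
      classify_acquisition(attach_admissions(mk_course(start, stop), adms))))
  }
  c1 <- prep("2020-06-01T08:00", "2020-06-10T10:00")
  expect_identical(c1$post_discharge_days, 5L)
  expect_equal(c1$post_discharge_pct, 50)
  c2 <- prep("2020-06-01T08:00", "2020-06-05T10:00")
  expect_identical(c2$post_discharge_days, 0L)
  expect_equal(c2$post_discharge_pct, 0)
  c3 <- prep("2020-06-05T10:00", "2020-06-08T10:00")  # continues after discharge
  expect_identical(c3$post_discharge_days, c3$lot_days - 1L)
  # outpatient continuation lying entirely after discharge: 100% of LOT
  c4 <- compute_lot(mk_course("2020-06-02T10:00", "2020-06-08T10:00"))
  c4$admission_id <- "A9"
  c4$discharge_ts <- pt("2020-06-01T18:00")
  c4 <- compute_post_discharge(c4)
  expect_identical(c4$post_discharge_days, c4$lot_days)
  expect_equal(c4$post_discharge_pct, 100)
})

test_that("exclusion cascade applies reasons in order with conserved counts", {
  adms <- dplyr::bind_rows(
    mk_adm("A1", "2020-06-01T00:00", "2020-06-10T10:00", pid = "P1"),
    mk_adm("A2", "2020-06-01T00:00", "2020-06-01T10:00", pid = "P2"),
    mk_adm("A3", "2020-06-01T00:00", "2020-06-10T10:00", pid = "P3", age = 9),
    mk_adm("A4", "2020-06-01T00:00", "2020-06-10T10:00", pid = "P4", icu = TRUE),
    mk_adm("A5", "2020-06-01T00:00", "2020-06-08T10:00", pid = "P5"),
    mk_adm("A5b", "2020-06-10T08:00", "2020-06-12T10:00", pid = "P5"),
    mk_adm("A6", "2020-06-01T00:00", "2020-06-10T10:00", pid = "P6")
  )
  courses <- dplyr::bind_rows(
    mk_course("2020-06-01T08:00", "2020-07-20T10:00", pid = "P1", id = "P1-1"),
    mk_course("2020-06-01T02:00", "2020-06-04T10:00", pid = "P2", id = "P2-1"),
    mk_course("2020-06-01T08:00", "2020-06-04T10:00", pid = "P3", id = "P3-1"),
    mk_course("2020-06-01T08:00", "2020-06-04T10:00", pid = "P4", id = "P4-1"),
    mk_course("2020-06-05T08:00", "2020-06-15T10:00", pid = "P5", id = "P5-1"),
    mk_course("2020-06-01T08:00", "2020-06-04T10:00", pid = "P6", id = "P6-1")
  )
  courses <- compute_post_discharge(compute_lot(
    classify_acquisition(attach_admissions(courses, adms))))
  res <- apply_exclusions(courses, adms, quiet = TRUE)
  reason <- function(id) {
    res$courses$exclusion_reason[res$courses$course_id == id]
  }
  expect_identical(reason("P1-1"), "duration_over_45d")  # LOT 50
  expect_identical(reason("P2-1"), "admission_under_12h")
  expect_identical(reason("P3-1"), "pediatric")
  expect_identical(reason("P4-1"), "icu_during_admission")
  expect_identical(reason("P5-1"), "readmitted_during_course")
  expect_true(is.na(reason("P6-1")))
  flow <- res$flow
  expect_identical(flow$n[flow$step == "input"],
                   flow$n[flow$step == "remaining"] +
                     sum(flow$n[!flow$step %in% c("input", "remaining")]))
  expect_identical(nrow(res$included), 1L)
})

test_that("a readmission under the 12 h minimum does not trigger exclusion", {
  adms <- dplyr::bind_rows(
    mk_adm("A1", "2020-06-01T00:00", "2020-06-08T10:00"),
    mk_adm("A2", "2020-06-10T08:00", "2020-06-10T14:00")  # 6 h only
  )
  courses <- compute_post_discharge(compute_lot(classify_acquisition(
    attach_admissions(mk_course("2020-06-05T08:00", "2020-06-15T10:00"), adms))))
  res <- apply_exclusions(courses, adms, quiet = TRUE)
  expect_true(is.na(res$courses$exclusion_reason))
})

test_that("flow conservation and CA/HA partition hold on a full synthetic cohort", {
  sim <- default_cohort()
  res <- default_build()
  flow <- res$flow
  expect_identical(flow$n[flow$step == "input"],
                   flow$n[flow$step == "remaining"] +
                     sum(flow$n[!flow$step %in% c("input", "remaining")]))
  expect_identical(flow$n[flow$step == "input"], nrow(res$courses))
  # the included set equals the set with no exclusion flags at all, so
  # inclusion does not depend on the order in which reasons are applied
  expect_setequal(res$included$course_id,
                  res$courses$course_id[res$courses$exclusion_flags == ""])
  expect_true(all(res$included$acquisition %in% c("CA", "HA")))
  ok <- !is.na(res$courses$post_discharge_days)
  expect_true(all(res$courses$post_discharge_days[ok] >= 0))
  expect_true(all(res$courses$post_discharge_days[ok] <=
                    res$courses$lot_days[ok]))
})
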