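---
title: "Measuring antibiotic treatment duration from EHR prescription data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antibiotic treatment duration from EHR prescription data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotsurv)
```

## The surveillance problem

Antimicrobial stewardship programs need to know, continuously and for
every treated infection in a hospital, how long antibiotic treatment
actually lasted and for what indication. Point-prevalence surveys and
chart review answer this for a sample at great cost; prescription
records in the electronic health record (EHR) contain the answer for
everyone, but not in usable form. A single clinical treatment episode is
scattered over many prescription orders — agents switched, doses
adjusted, intravenous changed to oral, inpatient orders continued as
outpatient prescriptions after discharge — and interleaved with orders
that are not treatment at all: surgical and long-term prophylaxis,
non-antibacterial drugs, prescriptions that were never formally stopped.

`lotsurv` turns three raw extracts — prescriptions (with the indication
recorded by the prescriber through a mandatory registration tool),
admissions, and optionally manual review verdicts — into per-patient
*treatment courses* with a definitive indication, a length of treatment
(LOT), an acquisition class, and a post-discharge share, and it manages
the stratified sampling and error accounting used to validate such a
dataset against clinical notes. Because no real hospital extract can be
shipped, the package also contains a synthetic EHR generator with known
ground truth that exercises every processing rule.

## From prescriptions to courses

The pipeline (`build_courses()`) applies, in order:

1. **Therapeutic filtering** (`filter_therapeutic()`). Only systemic
   antibacterials — ATC codes starting `J01` — participate.
   Prescriptions registered as prophylaxis are removed *before*
   assembly, so they can neither seed a course nor extend one.
2. **Presumed-prophylaxis removal** (`is_presumed_prophylaxis()`). Some
   prophylactic prescriptions arrive unlabelled. An unlabelled
   prescription of azithromycin, clarithromycin, doxycycline,
   erythromycin, fosfomycin, nitrofurantoin, pheneticillin or
   trimethoprim is presumed prophylactic when its inclusive calendar
   span exceeds 28 days. Co-trimoxazole
   (trimethoprim/sulfamethoxazole) is presumed prophylactic at daily
   doses of 480 mg or lower when prescribed for more than 14 days, and
   at higher doses for more than 50 days. All thresholds are strict
   (`> 28`, not `>= 28`) and configurable via `prophylaxis_rules()`.
   The rule applies only to *unlabelled* prescriptions: a prescription
   the clinician explicitly registered as therapy is never reclassified
   by duration, since genuinely long treatments (bone and joint
   infections, endocarditis) would otherwise be destroyed.
3. **Assembly by the 24-hour gap rule** (`assemble_courses()`). Per
   patient, prescriptions are sorted by start time (ties broken by
   prescription id for determinism) and greedily linked: a prescription
   joins the open course when its start lies at most 24 h after the
   course's latest *effective stop*; otherwise a new course opens. The
   comparison is inclusive — a gap of exactly 24 h still links. The gap
   is measured against the running maximum of member stops, not
   pairwise between adjacent orders, so overlapping and nested
   prescriptions always share a course. Outpatient prescriptions after
   discharge participate identically, which is what makes post-discharge
   duration visible. This greedy rule is provably equivalent to taking
   connected components of the interval graph whose edges join
   prescriptions with a gap of at most 24 h; the test suite checks the
   equivalence against a brute-force oracle on 1000 randomized
   instances of up to 15 prescriptions.
4. **Missing stop dates** (`effective_stop()`). Prescriptions that were
   never formally stopped have no stop timestamp. Such a prescription
   contributes only its start *date* (taken at start of day): a course
   ending on one is truncated to the start date of its last
   prescription and flagged `truncated_missing_stop`, rather than
   extended indefinitely. When a later prescription with a real stop
   exists, the real stop defines the course end and no truncation is
   flagged.
5. **Indication resolution** (`resolve_indications()`). The indication
   of the earliest-starting labelled member is the working diagnosis at
   the start of the course; the indication of the latest-starting
   labelled member is the *definitive indication* — the course's final
   diagnosis. If several members share that latest start time and carry
   distinct indications the course is flagged
   `multiple_final_diagnoses`; the "distinct labels at the same latest
   start" reading is the narrowest implementable definition of an
   ambiguous final diagnosis, and the flag only routes the course to
   exclusion, so a broader reading would change attribution, not
   inclusion. Open-text indications (and courses with no indication at
   all) are flagged `open_text_indication`.

## Classification and measurement

* **Admission linkage** (`attach_admissions()`): a course links to the
  admission window containing its start; treatment begun in an ER visit
  that turned into an admission therefore links to that admission. A
  course started shortly *before* admission and continued in hospital is
  linked to the first overlapping admission and flagged
  `pre_admission` — these are kept (as community-acquired) because
  dropping them would invent an exclusion the surveillance definition
  does not contain. Courses touching no admission are
  `not_hospital_initiated` and excluded.
* **Acquisition** (`classify_acquisition()`): community-acquired (CA)
  when treatment started less than 48 h after admission,
  hospital-acquired (HA) when later. Exactly 48 h is classified HA —
  the boundary itself is undefined by the "< 48 h" / "> 48 h"
  convention, and HA is the conservative nosocomial attribution. The
  boundary is configurable in `lot_thresholds()`.
* **LOT** (`compute_lot()`): the inclusive span of calendar days from
  the course start date to the stop date, irrespective of how many
  agents or doses are given per day. A course from 22:00 on day 1 to
  08:00 on day 3 has LOT 3.
* **Post-discharge share** (`compute_post_discharge()`): the number of
  course days strictly after the discharge date, and that number as a
  percentage of LOT.

## The exclusion cascade

`apply_exclusions()` evaluates, in fixed order: not hospital-initiated;
admission shorter than 12 h (the minimum duration that counts as a
hospitalization); pediatric patient (age < 18 at admission, the usual
adult-care boundary — the threshold is configurable because "pediatric"
is institution-defined); ICU stay during the admission (any ICU stay,
not temporal overlap with the course); multiple final diagnoses;
open-text indication; LOT over 45 days (computed LOT, after missing-stop
truncation); and readmission during the course, where the readmission
must itself satisfy the 12 h minimum to count as a hospitalization.
Criteria overlap; each course is attributed to its *first* matching
reason, and the flow table satisfies strict conservation
(`n_input = n_remaining + sum(n_excluded)`) on every run. Because a
course is included exactly when *no* criterion matches, the included set
is invariant under reordering — only the attribution changes.

The over-45-days and readmission exclusions exist because semi-automatic
LOT extraction is unreliable there (never-stopped prescriptions
accumulate in long courses; readmissions splice unrelated therapy into
one course), which is also why the validation workflow samples extended
courses at a higher rate *before* that exclusion is applied.

## Summaries, sampling and error rates

`summarize_courses()` reports, per definitive indication and acquisition
class: n, share of the class, median LOT with interquartile range, the
share of courses with any post-discharge treatment, and the mean
post-discharge percentage of LOT among those. Quantiles use linear
interpolation between order statistics (type 7, the ubiquitous default;
no other convention is implied by the day-count data). Percentages are
rounded half-up to one decimal, matching surveillance-report
presentation; half-up is implemented explicitly because base R rounds
half to even.

`draw_validation_sample()` draws a seeded, reproducible stratified
sample for manual chart review: 5% each of urinary tract, respiratory
tract and intra-abdominal infections, 5% of all remaining diagnoses,
and 20% of extended (> 45 day) courses, the extended stratum taking
precedence. Sample sizes are `round(fraction * stratum)` (half-up) with
a minimum of 1 in non-empty strata.

`compute_error_rates()` divides, per category and pooled, the number of
incorrect verdicts by the number of validated courses — for the
registered indication (overall, and at site level where UTI/RTI
sub-type errors are forgiven), for LOT against the prescriptions, and
for LOT against the clinical notes. Rates are always computed from the
verdict tallies, never transcribed from a report, so a published cell
whose printed percentage disagrees with its own numerator/denominator
will deliberately not be reproduced. `tabulate_error_causes()` breaks
the notes-level mismatches down by cause (hospital transfer, treatment
started before admission, mislabelled prophylaxis, outpatient parenteral
therapy, single-dose prescribing, other). The chart reading itself is
human work: the package manages its sampling and bookkeeping only.

## The synthetic EHR generator

`generate_ehr()` produces prescription and admission tables in the exact
input schemas, plus a ground-truth table stating what the pipeline
should find. Defaults are the study conditions the method assumes:

* a 73% community-acquired share;
* an indication mix and per-indication LOT distributions calibrated to
  hospital-wide surveillance of a large teaching hospital
  (`lot_reference()`); LOT is drawn from a discretized log-normal
  fitted per indication and acquisition class to the reference median
  and IQR (`meanlog = log(median)`,
  `sdlog = (log(q3) - log(q1)) / (2 z_{0.75})`) — the family is a
  modelling choice, made once, because only summary statistics are
  available to calibrate against;
* one admission and one intended course of 1–4 member prescriptions per
  patient, with intra-course gaps below 24 h and post-discharge
  continuation for 37.5% (CA) / 23.7% (HA) of multi-day courses —
  because a one-day course cannot straddle discharge, the realized
  cohort-level shares are a few points lower than these per-course
  rates;
* noise scenarios at rates chosen so each appears roughly 20+ times per
  1000 patients (test power, since real prevalence is unknown):
  prophylaxis-labelled prescriptions overlapping the course start or
  mid-course, trailing unlabelled long-duration prophylaxis, missing
  stop dates, non-J01 co-medication, open-text indications, multiple
  final diagnoses, pediatric/ICU/short admissions, readmission during
  the course, courses over 45 days, and courses started before
  admission.

The ground truth is derived by an independent, scalar application of the
surveillance rules to the intended course members — not by running the
pipeline — so end-to-end recovery (`compare_to_truth()`) is a real
two-route check. With all noise scenarios at default rates, the pipeline
recovers 100% of course boundaries, definitive indications, acquisition
classes, LOT values and exclusion reasons on a 1000-patient cohort; the
test suite and `scripts/acceptance.R` both re-verify this, and 1000
patients is the routine problem size used throughout because every
scenario is then well represented while a full run stays fast.

`inject_scenario()` adds a named scenario around a chosen course, with
the expected behaviour recorded. One scenario is deliberately
unrecoverable: `B2_unlisted` appends a trailing unlabelled prescription
of a drug *outside* the presumed-prophylaxis list. The duration rule
cannot see it, the course is extended, and the test suite asserts that
recovery *fails* — documenting the method's boundary rather than hiding
it.

What the generator does **not** emulate, and passing tests therefore do
not show: transfers between hospitals (treatment started or continued
elsewhere is invisible in a single EHR), outpatient parenteral therapy
not captured as prescriptions, free-text clinical notes (reviewer
verdicts are an input, never computed), clinically realistic drug choice
per indication, and date-only source extracts — timestamps are assumed
at minute resolution in a single implicit timezone, and date-only inputs
(parsed as midnight) coarsen the 24 h and 48 h rules accordingly.

## Numerical and degenerate-input choices

* Timestamps: ISO 8601 at minute resolution, one implicit timezone;
  calendar dates by truncation. The method counts calendar days, so
  timezone arithmetic would add complexity without information.
* Ties at assembly are broken by (start time, prescription id): stable
  and deterministic.
* The co-trimoxazole threshold of 480 mg is interpreted as total daily
  dose — 480 mg/day is the standard prophylactic dose, and
  prophylaxis is what the rule detects.
* A single prescription with no stop date yields a one-day course whose
  stop (start of the start date) can precede its own start timestamp;
  LOT is still 1 and downstream arithmetic is unaffected.
* Empty inputs propagate: zero prescriptions produce zero courses, a
  header-only output file, and an all-zero conserved flow.
* Readers never silently drop rows: every malformed row aborts with its
  data row number, and unknown vocabulary values are mapped to
  open-text with a warning so they route to exclusion rather than
  vanishing.

## Worked example

```{r example, eval = FALSE}
res <- build_courses(example_prescriptions(), example_admissions())
res$courses[c("course_id", "acquisition", "lot_days",
              "post_discharge_days", "definitive_focus")]
summarize_courses(res$included)
```

## Known limitations

The method measures what the EHR recorded, not what the patient
received: therapy around transfers, OPAT and pre-admission treatment is
systematically mismeasured, which is exactly why the validation
workflow and its error accounting are part of the package. The
presumed-prophylaxis rule is a drug list — an unlabelled prophylactic
prescription of an unlisted drug extends a course (see `B2_unlisted`
above). And the definitive-indication convention attributes the whole
course to the last registered indication, which under-counts treatment
given under an earlier working diagnosis.
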