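# lotsurv

Semi-automated surveillance of antibiotic treatment duration from raw
EHR prescription data, for antimicrobial stewardship teams.

Hospitals that want to monitor guideline adherence — above all, whether
infections are treated *too long* — need the length of treatment (LOT)
and the indication for every antibiotic course in the house, including
hospital-acquired infections and the part of therapy continued after
discharge. That information exists in the EHR, but scattered: one
clinical treatment episode spans many prescription orders, interleaved
with prophylaxis and co-medication. `lotsurv` reconstructs it.

## Method

Given a prescription extract (with prescriber-registered indications), an
admission table and, optionally, manual chart-review verdicts, the
package:

1. **filters to therapeutic antibacterials** — ATC class `J01`, minus
   prescriptions registered as prophylaxis, minus *presumed* prophylaxis:
   unlabelled prescriptions of a fixed drug list (azithromycin,
   clarithromycin, doxycycline, erythromycin, fosfomycin, nitrofurantoin,
   pheneticillin, trimethoprim) spanning more than 28 days, and
   co-trimoxazole at ≤ 480 mg/day for more than 14 days or at higher
   doses for more than 50 days;
2. **assembles treatment courses** by the 24-hour gap rule: per patient,
   a prescription starting no more than 24 h after the course's latest
   effective stop joins the course (greedy linkage, provably equal to
   connected components of the ≤ 24 h-gap interval graph); prescriptions
   with a missing stop date contribute only their start date, truncating
   the course there;
3. **resolves indications**: the last-registered indication within a
   course is its definitive (final) diagnosis;
4. **classifies acquisition**: community-acquired (CA) when treatment
   started < 48 h after admission, hospital-acquired (HA) otherwise, and
   computes LOT — the inclusive calendar-day span, irrespective of the
   number of agents per day — and the post-discharge share;
5. **applies an exclusion cascade** with strictly conserved counts
   (non-hospital-initiated, admission < 12 h, pediatric, ICU, multiple
   final diagnoses, open-text indication, LOT > 45 days, readmission
   during the course);
6. **summarizes and validates**: per-indication × acquisition medians and
   IQRs, seeded stratified sampling for chart review (5% per major
   infection group, 20% of extended courses), and error-rate reports
   (indication, LOT vs prescriptions, LOT vs notes, with cause
   breakdown).

A synthetic EHR generator (`generate_ehr()`) emits raw tables with known
ground truth — including prophylaxis overlaps, trailing unlabelled
prophylaxis, missing stop dates, readmissions and all other complexity
scenarios — so the whole pipeline is testable end to end without
hospital data. See the methods vignette
(`vignettes/surveillance-methods.Rmd`) for the full model description
and design rationale.

## Worked example

The package ships a tiny illustrative extract: three patients, eight
prescriptions — among them a paracetamol order (non-J01), a
prophylaxis-labelled cefazolin overlapping a course start, a 35-day
unlabelled nitrofurantoin tail, and a prescription without a stop date.

```r
library(lotsurv)
res <- build_courses(example_prescriptions(), example_admissions())
#> therapeutic filter: kept 5 of 8 (removed 1 non-J01, 1 labelled prophylaxis, 1 presumed prophylaxis)
#> assembled 3 course(s) from 5 prescription(s) for 3 patient(s)
#> exclusions: 3 course(s) in, 0 excluded, 3 remaining

res$courses[c("course_id", "acquisition", "lot_days",
              "post_discharge_days", "definitive_focus")]
#>   course_id acquisition lot_days post_discharge_days definitive_focus
#> 1    P001-1          CA        8                   3              UTI
#> 2    P002-1          HA        8                   1              RTI
#> 3    P003-1          CA        1                   0 skin/soft tissue
```

Patient P001 entered through the ER (CA); two linked prescriptions give
an 8-day course for a complicated urinary tract infection, 3 days of it
after discharge. Patient P002 started treatment 72 h into an admission
(HA, hospital-acquired pneumonia); the trailing nitrofurantoin
prescription was recognized as presumed prophylaxis and did not extend
the course. Patient P003's only prescription lacks a stop date, so the
course is truncated to its start date (LOT 1) and flagged.

```r
summarize_courses(res$included)[c("indication", "acquisition", "n",
                                  "lot_median", "lot_q1", "lot_q3")]
#>         indication acquisition n lot_median lot_q1 lot_q3
#> 1          RTI-HAP          HA 1          8      8      8
#> 2  UTI-complicated          CA 1          8      8      8
#> 3 skin/soft tissue          CA 1          1      1      1
```

A command-line front end wraps the same functions as subcommands
(`simulate`, `build`, `summarize`, `sample`, `errors`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "lotsurv.R", package = "lotsurv"))')" \
  simulate --n-patients 1000 --seed 1 --out out/
```

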