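Package: lotsurv
Title: Semi-Automated Surveillance of Antibiotic Treatment Duration from EHR Prescription Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw electronic health record (EHR) extracts of
    antibiotic prescriptions, registered indications and hospital
    admissions into per-patient treatment courses for antimicrobial
    stewardship surveillance. Implements therapeutic filtering on ATC
    class J01, rule-based removal of presumed prophylaxis, assembly of
    prescriptions into courses by a 24-hour gap rule, classification of
    community- versus hospital-acquired infection at a 48-hour boundary,
    length-of-treatment (LOT) computation in calendar days including the
    post-discharge period, a conserved exclusion cascade, surveillance
    summaries, stratified validation sampling with error-rate reporting,
    and a synthetic EHR generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
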