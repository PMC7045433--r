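Package: mhcasefind
Title: Case Identification of Mental Health Problems in Children and
    Young People from Linked Administrative Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-source case-identification (computational
    phenotyping) method for mental health and related problems in children
    and young people aged 0-24, of the kind used with New Zealand's linked
    administrative health collections. Coded events from five data sources
    (specialist mental-health diagnoses and activity, hospital discharges,
    pharmaceutical dispensings, disability-support referrals, and mortality)
    are mapped through an age-restricted codebook to 13 problem categories,
    collapsed to per-person dichotomous indicators with a precedence rule,
    and tabulated as confidentialised category-by-source counts and
    12-month prevalence rates per 100,000 against a constructed resident
    denominator population. Includes graduated random rounding to base 3
    with small-cell suppression, and a synthetic-data generator with known
    ground truth for validating the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
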