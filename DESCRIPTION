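Package: ocspatterns
Title: Classification of Intermittent Oral Corticosteroid Use Patterns in Asthma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for pharmacoepidemiological analysis of oral
    corticosteroid (OCS) prescribing in asthma from tabular electronic
    health records. Implements a stepwise, specificity-maximising
    algorithm labelling each OCS prescription as intermittent or
    long-term from dosing instructions, prednisolone-equivalent daily
    dose, concurrent respiratory events and annual prescription counts;
    sequences inter-prescription gaps of intermittent-only patients into
    frequency categories (frequent, moderately frequent, infrequent,
    sporadic) and a detailed combination taxonomy; builds eligible
    cohorts with full attrition logging; stratifies patterns by GINA
    2020 treatment step, SABA fills and age band with chi-square
    contingency summaries; and generates synthetic cohorts with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
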