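Package: collarEE
Title: Behavior Classification and Energy Expenditure from Livestock Collar Accelerometry
Version: 0.1.0
Authors@R:
    person("Collar", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processes tri-axial collar accelerometry from grazing ruminants into
    behavior-resolved energy-expenditure reports. Removes gravity by sample
    differencing, computes dynamic body acceleration metrics (ODBA, VeDBA),
    classifies a five-state ethogram (eating, lying, ruminating, standing,
    walking) with a decision-tree classifier, aggregates to one-minute
    intervals (mean VeDBA, predominant behavior, ambient temperature), and
    applies behavior-conditioned energy equations to produce hourly time
    budgets and daily per-behavior energy reports. Includes a seeded synthetic
    collar-data simulator (diurnal behavior schedule, gait and jaw
    periodicity, orientation drift, temperature trace) so the full pipeline is
    testable offline, and a command-line interface tying the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
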