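Package: spendseg
Title: Monthly Spending-Order Segmentation of High-Cost Insurance Expenditures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments high-cost health-insurance expenditures by ranking each
    beneficiary's months from highest to lowest spend, aggregating spend and
    headcounts into a month-by-rank segment grid, and tracking the migration of
    the highest-segment subgroups across months. Includes readers for
    claim-level and eligibility tables, a yearly-concentration module for
    selecting the top-fraction high-cost cohort, a seeded synthetic claims
    generator emulating heavy-tailed spending with episodic monthly spikes and
    decedent truncation, and a command-line pipeline that exports all grids and
    figure-ready data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
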