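Package: nutricost
Title: Costing Nutrition-Specific Intervention Packages at Full Coverage
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A program-experience costing engine for national and subnational
    budgeting of direct nutrition interventions. Projects census-style
    demographic inputs to a target year, derives beneficiary cohorts
    (children by age band, pregnant and lactating women, adolescents,
    households), resolves intervention-specific target populations from
    declarative eligibility rules (prevalence filters, incidence multipliers,
    endemic-area restrictions, programme exclusions), normalizes
    heterogeneous unit-cost expressions (per day, per visit, per household,
    per case, INR or USD) to US dollars per beneficiary-year, and computes
    annual full-coverage delivery costs with aggregation by intervention,
    category, region and scenario, percentage cost shares, scenario
    comparison and one-way sensitivity swaps. Ships declarative scenario
    configurations for a ten-intervention global package and a
    fifteen-intervention India-specific package, a packaged India 2014
    national and state fixture back-derived from published programme costs,
    and a synthetic census-style data generator for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
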