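Package: ssbreform
Title: Microsimulation of Added-Sugar Reformulation in Sugar-Sweetened
    Beverages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate the population health impact of gradually
    reformulating sugar-sweetened beverages (SSBs) to reduce their added
    sugar content. The package computes the individual-level sugar
    reduction compatible with a 10%-of-energy added-sugar goal, schedules
    the reduction over a multi-year rollout (decreasing, constant, or
    increasing yearly steps), converts it to a net caloric change under
    partial dietary compensation, propagates the change through the
    Chow-Hall dynamic energy-balance body-weight model for every adult in
    a survey sample, and aggregates results to survey-weighted changes in
    weight, BMI, and BMI-category prevalence with projected case counts.
    A seeded synthetic-population generator emulating a national dietary
    survey makes the full pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
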