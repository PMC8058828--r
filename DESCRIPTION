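Package: fopflcaries
Title: Microsimulation of Front-of-Package Food Labeling Effects on Dental Caries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytical microsimulation of the impact of
    front-of-package food labeling on dental caries in an adult population,
    stratified by sex and age band. Simulates individuals through yearly
    cycles of a two-state (no-caries/caries) model under a baseline and a
    labeling scenario, links the labeling-induced reduction in added-sugar
    intake to annual caries incidence through a dose-response slope, and
    values prevented lesions as restoration costs avoided, disability-adjusted
    life years (DALYs) averted, and productivity losses avoided, with annual
    discounting. Includes deterministic and probabilistic sensitivity
    analysis with cost-effectiveness-plane output, a synthetic generator of
    plausible German-like survey inputs, and an audit of arithmetic
    identities among published reference results.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
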