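Package: invasim
Title: Species Invasions in Competition-Colonisation Tradeoff Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating species invasions in patch-occupancy
    metacommunities structured by a competition-colonisation tradeoff.
    Generates ensembles of stably coexisting communities by seeded rejection
    sampling, moves a designated species off the tradeoff surface via
    sustained or pulsed external propagule supply (cultivation) and/or
    reduced mortality (enemy release), optionally elevates community-wide
    disturbance, and quantifies the resulting native extinctions over time
    and across ensembles with quantile-envelope summaries. Equilibria are
    obtained by a closed-form sequential solver and cross-checked against
    stiff ODE integration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
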