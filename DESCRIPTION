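Package: waggleforage
Title: Agent-Based Simulation of Honeybee Colony Foraging with
    Waggle-Dance Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spatially explicit individual-based model of central-place
    nectar foraging in a honeybee colony. Scouts find stochastic forage
    patches by Levy-flight search and advertise them with waggle dances
    that either communicate the patch location (spatial information, SI)
    or merely activate nestmates to scout (no spatial information, NI).
    Recruits revisit profitable patches across days, so recruitment pays
    off long after the dance and contaminates SI/NI crossover
    experiments. Includes the switching experimental designs, replicate
    statistics (relative benefit of spatial information, per-capita
    foraging efficiency, Poisson site persistency, carry-over profiles)
    and reproducible experiment runners.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
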