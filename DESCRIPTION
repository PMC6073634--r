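Package: gardsim
Title: Simulation and Analysis of Graded Autocatalysis Replication Domain (GARD) Protocell Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic kinetic simulation of mutually catalytic amphiphile
    assemblies under the graded autocatalysis replication domain (GARD) model:
    lognormal rate-enhancement matrices, Gillespie dynamics of monomer entry
    and exit, growth-fission reproduction, composome and compotype detection,
    compositional-information and entropy metrics, constant-population reactor
    experiments (compound depletion screens, environment shifts, compotype
    takeovers), chiral symmetry breaking, a minimal dimer-level polymer
    extension, and planetary-scale combinatorics calculators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nortest,
    withr
Config/testthat/edition: 3
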