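Package: beebreed
Title: Stochastic Simulation of Honeybee Breeding Programs with Controlled Mating
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of closed honeybee (Apis mellifera) breeding
    populations under different mating-control strategies: isolated mating
    stations stocked with sister groups of drone-producing queens, and
    instrumental insemination with drones from a single colony at two- or
    three-year (or mixed) paternal generation intervals. A finite-locus genetic
    model with maternal (queen) and direct (worker) effects drives colony
    phenotypes; selection uses best linear unbiased prediction on the
    pedigree-accessible relationship matrix while realized inbreeding is
    tracked on the true relationship matrix with known individual drone
    fathers. Includes the analytic layer for breeding-scheme comparison:
    effective number of sires from paternal identity-by-descent probabilities,
    generational inbreeding rates, Wright's effective population size,
    generation intervals, and Welch tests over simulation replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
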