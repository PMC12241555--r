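Package: demosmc
Title: Demographic Inference with Coalescent Simulation, Neural-Network
    Summaries, ABC and Sequential Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation-based inference for multi-population demographic
    history with archaic introgression. Compiles parameterized out-of-Africa
    demographic models (population splits, bottlenecks, exponential growth,
    Neanderthal/Denisovan admixture pulses, optional ghost lineages and
    migration) into a structured-coalescent simulator, summarizes genotype
    data as cross-population site frequency spectra (cSFS), trains compact
    neural networks on simulated reference tables, and performs model choice
    and parameter estimation by rejection ABC on the network outputs with
    sequential Monte Carlo prior refinement. Also estimates time-binned
    within- and cross-population coalescence rates and relative
    cross-coalescent rate (RCCR) curves from the true simulated genealogies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    GenomeInfoDb
Config/testthat/edition: 3
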