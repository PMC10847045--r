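Package: rhizodeb
Title: Genome-Informed Trait-Based Dynamic Energy Budget Models of Soil Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates genome-derived traits of soil bacterial isolates
    (genome size, rRNA operon copy number, genome-inferred maximum specific
    growth rate, transporter and glycoside hydrolase gene frequencies) into a
    fully parameterized dynamic energy budget (DEB) model of growth on
    root-exudate metabolites. Substrate uptake follows diffusion-limited
    kinetics under the equilibrium chemistry approximation (ECA) for
    multi-substrate, multi-consumer networks; assimilation yields follow a
    thermodynamic coupling of catabolism and anabolism driven by the nominal
    oxidation state of substrate carbon. Batch and mixed-medium growth are
    integrated as stiff ODE systems, and emergent phenotypes (realized growth
    rate, carbon use efficiency, latency, niche breadth, biomass
    production-respiration scaling) are summarized with tidy analysis verbs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
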