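Package: plasso
Title: Pierced Lasso Topology Detection and Structure-Based Folding Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and classifies disulphide-closed covalent-loop (pierced
    lasso) topologies in protein structures, generates idealized four-helix
    bundle test systems, builds coarse-grained Calpha structure-based (Go-type)
    models under three disulphide oxidation states (reduced, oxidized,
    dynamic), integrates them with Langevin dynamics and umbrella sampling,
    and analyses folding thermodynamics (WHAM specific heat, folding
    temperatures), threading mechanisms (slipknotting versus plugging), and
    native-state slow-mode dynamics from principal component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
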