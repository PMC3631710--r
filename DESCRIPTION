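Package: LithoMet
Title: Catabolic Free-Energy Landscapes and Functional-Gene Abundance for
    Chemolithotrophic Ecosystems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether the energy available from redox
    reactions in an environment predicts the microbial metabolisms found
    there. Computes in-situ Gibbs free energies of catabolic reactions from
    field water chemistry (extended Debye-Hueckel and Setchenow activity
    corrections, Henry's-law dissolved-gas maxima, van't Hoff equilibrium
    constants), quantifies functional-gene families in annotated shotgun
    metagenome hit tables as normalized relative abundances with binomial
    confidence intervals, estimates per-taxon genome coverage of a
    metagenome library under a Poisson model, and simulates all required
    inputs from communities with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
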