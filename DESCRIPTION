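Package: dlgradient
Title: Compartmental Reaction-Transport Modeling of the Dorsal Nuclear
    Gradient in Drosophila Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the formation of the maternal Dorsal (NF-kB) nuclear
    concentration gradient in the syncytial Drosophila blastoderm as a ring of
    cytoplasmic compartments exchanging Dorsal, Cactus and the Dorsal-Cactus
    complex, with a space-dependent Toll-driven dissociation rate peaking at
    the ventral midline. Ships published parameter sets for wild type, ploidy
    and dosage mutants and six Drosophila species; provides the
    30-most-ventral-nucleus window extraction, min-max and peak normalization,
    the root-sum-of-squares fit distance, t-based confidence intervals,
    two-parameter sensitivity scans with contour levels, linear rescaling of
    the Toll amplitude by mesodermal arc-length, multicycle simulations with
    division events, and a synthetic replicate-embryo cohort generator for
    testing the fitting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
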