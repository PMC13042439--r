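Package: qmregion
Title: Electronically Informed QM/MM Region Selection from Fragment
    Molecular Orbital Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for defining the quantum region of hybrid QM/MM
    calculations from ligand-induced electronic responses. Per-fragment
    HOMO-LUMO gap shifts and charge redistribution between the guest-free
    (apo) and guest-bound (holo) states are extracted from a fragment
    molecular orbital (FMO) style calculation and turned into a convergence
    radius, a charge-flow network with hub-fragment detection, and concrete
    QM-region definitions (empirical, short-range, MO-based). A
    self-contained one-orbital self-consistent-charge tight-binding engine
    makes the whole pipeline runnable at desk scale, and benchmark helpers
    compare region models against all-QM references, including rank
    agreement with experimental activities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
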