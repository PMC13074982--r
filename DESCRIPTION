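Package: mpqsar
Title: QSAR Models for Adsorption of Organic Pollutants onto Microplastics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular-graph autocorrelation (Broto-Moreau and Moran) and
    Burden-matrix BCUT descriptors computed from SMILES, a multiple linear
    regression pipeline with leave-one-out and external validation,
    y-randomization and leverage-based applicability-domain analysis, and
    six ready-to-use models predicting aqueous adsorption energies of
    organic pollutants on polyethylene, polyoxymethylene and polyvinyl
    alcohol microplastics. Ships the underlying 54-compound adsorption
    energy dataset with curated SMILES.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
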