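Package: cellaflux
Title: Constraint-Based Metabolic Modelling of the Facultative Methanotroph
    Methylocella silvestris
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale constraint-based analysis of the
    facultative methanotroph Methylocella silvestris: flux balance analysis
    with parsimonious refinement, substrate-uptake minimisation at fixed
    growth rate, maximal-yield computation, non-growth-associated ATP
    maintenance fitting, gene-deletion phenotype screens over substrate
    panels, energy-cycle quality control, flux-proteome Pearson correlation
    with false-discovery-rate control, metabolite connectivity statistics,
    and biomass-yield estimation from growth curves.  Models are read and
    written in SBML (Level 3 'fbc' and SEED-style Level 2) and a
    tab-separated table dialect.  Includes a hand-curated mini-model of
    Methylocella central carbon metabolism (serine cycle, glyoxylate shunt,
    dual propane oxidation pathways) and generators for synthetic toy
    models, proteomes and growth series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
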