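Package: glutenquant
Title: Peptide-Centric Gluten Quantitation and Immune-Epitope Abundance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for peptide-centric relative quantitation of wheat gluten
    and related allergen proteins from targeted mass-spectrometry (MRM) peak
    areas. Provides in-silico protease digestion and proteotypic peptide
    selection, transition-level quality filtering and scheduled assay design,
    prolamin protein-family classification and peptide group allocation,
    cross-replicate normalization with group-level relative abundance and
    volcano statistics, exact-match immune-epitope containment mapping with
    per-category abundance ratios, hypergeometric term overrepresentation,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
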