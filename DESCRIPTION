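Package: serotile
Title: Linear Epitope Mapping from Tiled Peptide-Microarray Serology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-content peptide microarrays that tile
    homologous allergen panels (such as fish beta-parvalbumin isoforms) with
    overlapping 16-mer peptides. Provides exhaustive peptide tiling and
    unique-peptide indexing, master-alignment coordinate mapping and
    per-column diversity profiling, Kolaskar-Tongaonkar antigenicity
    prediction, robust reactive-peptide calling with multi-sample and
    multi-peptide confirmation criteria, minimal-epitope deconvolution from
    runs of reactive tiles, residue-level attribution of binding differences
    across homologous isoforms, isoallergen-differential recognition,
    longitudinal induction detection, reactivity-profile PCA and clustered
    heatmap ordering, and a fully seeded synthetic serology generator with
    ground-truth recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
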