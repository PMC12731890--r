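Package: polarmeth
Title: Discovery of Polar Marginal DNA Methylation Markers from
    Beta-Value Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A marginal-filtering workflow for Illumina-style DNA
    methylation Beta-value matrices: detection p-value cleaning,
    cross-platform locus harmonization, classification of Beta values into
    extreme (near-0 / near-1) categories, and set-algebra discovery of
    "polar marginal" CpG loci that stably separate cell types within a
    group and cell groups from each other (for example endothelial versus
    leukocyte DNA). Includes probe-manifest annotation summaries
    (promoter, CpG island, shore, shelf and enhancer context), a
    quantile-normalization comparison check for cross-platform batch
    effects, and a synthetic two-platform methylome generator with a
    planted marker architecture for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite
Config/testthat/edition: 3
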