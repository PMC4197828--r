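Package: coexpipe
Title: Differential Expression, Constrained Mixture Co-Expression Clustering
    and Regulatory-Context Enrichment for Two-Colour Microarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis chain for two-colour (dye-swap) microarray
    immune transcriptomics: loess intensity-dependent normalisation, replicate
    averaging with dye-orientation handling, empirical-Bayes moderated t
    statistics, multiple-testing adjustment and MAPK-dependence calls;
    model-based co-expression clustering with a volume-varying shared-shape
    Gaussian mixture (EM, BIC model selection) and a misclassification-
    controlled threshold maximum a posteriori assignment rule; positional
    cis-element (preferentially located motif) detection and binomial
    cluster enrichment; GO and kinetic-class hypergeometric enrichment; and
    PPI / transcription-factor-target interaction network hub analysis.
    Includes a synthetic-data module that simulates every pipeline input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
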