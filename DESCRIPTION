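Package: sarloc
Title: Spatially Adjacent Regulated Genes from Chromosomal Interaction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcription-factor knockout-affected genes that are
    spatially adjacent regulated (SAR) genes: genes not bound by a factor but
    colocalized in the nucleus, via chromosomal interaction segments, with
    genes the factor does bind. Provides readers for the tabular inputs
    (gene annotation, interaction segment pairs, ChIP binding and knockout
    gene lists, flat GO-style annotations, expression matrices, promoter
    nucleosome occupancy, motif presence), the mutual-exclusion and linear
    proximity filters, gene-to-segment mapping, SAR classification with
    pooled colocalization frequencies, a chromosome-matched permutation test
    with empirical P values, downstream functional contrasts (cellular
    co-component, biological co-process, co-expression, expression
    variability) and chromatin contrasts (motif presence, promoter
    nucleosome occupancy, binding TF counts, binding affinity), plus a
    synthetic data generator with planted ground truth for end-to-end
    calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
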