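Package: methylDose
Title: Dose-Response Analysis of Chemically Induced DNA Demethylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing experiments in
    which plants are treated with increasing concentrations of nonmethylable
    cytosine analogs (5-azacytidine, zebularine). Computes context-resolved
    (CG/CHG/CHH) weighted methylation levels at genome, window, region and
    feature scale; treated-versus-control relative demethylation profiles;
    per-site methylation-level distributions; binomial-test classification of
    genes into gene-body-methylated (gbM), mCHG-enriched, mCHH-enriched and
    unmethylated classes; metagene methylation profiles over scaled gene
    bodies with fixed flanks; linear dose-response modelling of methylation
    against inhibitor concentration; a strict fold-change/q-value differential
    expression filter; and Fisher's exact enrichment of methylation classes
    and transposable-element families among upregulated genes. Includes a
    seeded synthetic methylome and expression generator with planted
    demethylation fractions, gene classes and enrichment effects so every
    stage of the pipeline can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
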