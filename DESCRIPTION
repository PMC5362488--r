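Package: lfq2mrm
Title: From Label-Free Discovery Proteomics to Scored Biomarker Panels and
    MRM Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for label-free quantitative (LFQ) proteomics
    biomarker studies with a replicate-structured design. Reads a
    MaxQuant-style protein-groups intensity matrix together with a sample
    design table, applies the standard identification filters (reverse hits,
    contaminants, only-identified-by-site, minimum peptide count), and
    computes replicate quality control: Pearson correlations, biological
    replicate overlap and per-protein coefficients of variation from sample
    and technical replicate injections. A differential layer provides log2
    transformation, left-censored constant imputation, per-group Student
    t-tests, one-way ANOVA with a Fisher least-significant-difference
    fold-change cutoff, PCA and z-scored Euclidean hierarchical clustering.
    Significant proteins are assembled into candidate biomarker panels gated
    on replicate CV, prioritised with an additive five-criterion evidence
    score, and exported as in-silico designed multiple reaction monitoring
    (MRM) transition lists via tryptic digestion, proteotypic peptide
    selection and singly charged y-ion m/z computation. A synthetic-data
    module generates all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
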