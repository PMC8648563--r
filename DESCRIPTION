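Package: envcci
Title: Microenvironment-Restricted Cell-Cell Communication Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers relevant ligand-receptor interactions between cell types
    from clustered single-cell RNA-seq count matrices, restricting tests to
    cell-type pairs that co-occur in user-declared tissue microenvironments.
    Supports heteromeric ligand and receptor complexes (scored by their
    least-expressed subunit), a sequencing-depth-stratified Wilcoxon
    rank-sum differential-expression test with Stouffer-combined Z-scores
    and Benjamini-Hochberg adjustment, an optional cluster-label permutation
    null for interaction scores, and a seeded negative-binomial simulator
    with planted markers and ligand-receptor pairs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
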