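Package: radmut
Title: Dose-Response, Mutation-Spectrum and Rearrangement-Junction Analysis
    for Radiation Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising radiation mutagenesis experiments in
    plants. Fits the single-hit multitarget survival model to seed
    dose-survival assays and derives D0, the extrapolation number, the
    shoulder dose and LD50; implements a threshold-burden model in which
    per-individual mutation load distributions shift with dose and survival
    is the probability of staying below a fixed tolerable burden; classifies
    single-base substitutions and small insertions/deletions by zygosity,
    substitution type, length class, junction sequence context, genomic
    region and coding consequence; reconstructs structural-variant junctions
    from reference and product sequences, measuring breakpoint microhomology
    and junction deletions to classify the end-joining mechanism (classical
    NHEJ versus microhomology-mediated end joining); aggregates published
    summary tables of phenotypic mutation rates and rearrangement events;
    and generates synthetic genomes, variant tables, survival datasets and
    junction cases with known ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
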