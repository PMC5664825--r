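Package: retroscan
Title: Detection and Dating of LTR-Retrotransposon-Mediated Retrogenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genes created by LTR-retrotransposon-mediated
    retroduplication (notably NLR disease-resistance genes) from genome
    annotations: candidate detection inside full-length and fragmented LTR
    elements, parental-gene verification by local alignment with a query
    coverage criterion, curation of false positives and false negatives
    (TE-conflict removal, multi-gene-per-element discrimination, orphan
    filtering, the normal-gene comparison set), retro-signature scanning
    (poly(A) tails, flanking direct repeats), and molecular-clock dating of
    LTR insertions (Kimura two-parameter distance between paired LTRs, K/2r)
    and gene duplications (Nei-Gojobori Ka/Ks, Ks/2r, single-linkage Ks
    clustering). Includes a synthetic-genome generator with a planted truth
    table so every stage is testable without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
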