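Package: sgmsig
Title: Stop-Gain Mutations and Single-Base-Substitution Mutational Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of protein-truncating stop-gain mutations (SGMs) in the
    context of single-base-substitution (SBS) mutational signatures. Provides
    codon-level enumeration of single-base paths to stop codons and
    signature-conditional amino-acid truncation propensities, functional
    annotation of somatic SNVs against a coding model, signature exposure
    refitting and per-SNV signature assignment, Fisher/Brown/FDR enrichment
    statistics for signature-by-class and gene-level tests, copy-number,
    motif, expression and smoking-history association tests, and a fully
    synthetic cohort simulator (signature-driven mutation placement in
    sequence context, driver-gene spiking, copy-number and clinical
    covariates) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    MASS,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
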