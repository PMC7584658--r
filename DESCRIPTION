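Package: promsub
Title: Promoter-Substitution Screening from Segmented Copy-Number Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers somatic intrachromosomal deletions and tandem duplications
    from SNP-array segmented copy-number (SEG) profiles, predicts
    promoter-substitution events (gene fusions and promoter-to-upstream
    juxtapositions) from the inferred breakpoints against a GENCODE-style gene
    model, and screens recurrently affected gene pairs for transcriptional
    induction of the 3' partner with Student's t-tests under
    Benjamini-Hochberg false-discovery-rate control. Includes concordance
    assessment against external whole-genome-sequencing structural-variant
    calls and a deterministic synthetic-cohort generator (purity/noise model
    for array amplitudes, planted rearrangements and expression effects) used
    to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
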