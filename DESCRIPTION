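Package: somaticmotifs
Title: Motif-Centered Analysis of Somatic Mutation Catalogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and quantifies the activity of known mutagenic
    processes in somatic single-nucleotide variant catalogues by testing
    for enrichment of mutations in short knowledge-based sequence motifs
    (e.g. the meCpG-deamination motif nCg->nTg, the APOBEC motif
    tCw->tTw/tGw, UV and alkylation motifs).  Enrichment is computed
    against the local +/-20 bp sequence context of each mutation, tested
    per sample with a one-sided Fisher exact test, gated by
    Benjamini-Hochberg FDR control, and converted into a Minimal
    Estimate of Mutation Load (MEML) attributable to each process.
    Additional tools dissect strand-coordinated mutation clusters,
    distinguish APOBEC3A-like from APOBEC3B-like deamination with a
    Breslow-Day homogeneity test, aggregate sample results to donors,
    and relate motif loads to donor age and disease status.  A
    seed-deterministic simulator generates reference genomes and
    mutation catalogues with controlled motif-targeted, clock-like and
    clustered mutational processes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
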