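Package: remethyl
Title: Tile-Based Analysis of DNA Methylation Loss and Recovery After
    Transient DNMT1 Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses reduced representation bisulfite
    sequencing (RRBS) experiments in which the maintenance
    methyltransferase DNMT1 is transiently suppressed and then
    re-expressed.  Provides a per-division maintenance/de-novo
    inheritance model of CpG methylation with a least-squares parameter
    estimator, a synthetic annotated genome generator with imprinted
    gDMD, gDMD-like, repeat and genic locus classes, 100 bp tile
    quantification with coverage filters, two differential-methylation
    recipes (replicate Welch t test and pooled-count Fisher exact test
    with Benjamini-Hochberg correction), demethylation/remethylation
    trajectory classification, candidate gene ranking by fractional
    methylation loss, genomic feature/CpG-island/repeat annotation with
    composition statistics, and an end-to-end pipeline with a
    consistency-checked summary report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    graphics,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
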