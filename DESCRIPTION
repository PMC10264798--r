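Package: ctcfcat
Title: Curation of CTCF Genotype-Phenotype Variant Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline that turns heterogeneous
    genotype-phenotype database exports of CTCF variants into a
    deduplicated, annotated catalog of variants associated with
    neurodevelopmental disorders. Includes chain-file genome liftover,
    HGVS coding-DNA parsing and 3'-rule normalization, transcript
    coordinate mapping and protein-consequence calling, zinc-finger
    domain and key-residue annotation, rule-based phenotype and
    pathogenicity classification, copy-number dosage and size analysis,
    and a synthetic multi-source data generator with a ground-truth
    ledger for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
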