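Package: ithexome
Title: Intratumoral Heterogeneity Analysis of Multiregion Tumor Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of intratumoral heterogeneity (ITH) from multiregion
    whole-exome sequencing of tumor/normal sample trios (non-tumor, central
    tumor, peripheral tumor). Implements rule-based somatic SNV and indel
    filtering with machine-readable reject reasons, common/private clonality
    classification by cross-sample read interrogation with orthogonal
    allele-frequency confirmation, mutation substitution spectra and CpG
    statistics, driver-mutation tiering against a curated knowledge base,
    and a panel-of-normals read-depth copy-number caller with tumor-purity
    adjustment. Ships a synthetic multiregion cohort generator with full
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
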