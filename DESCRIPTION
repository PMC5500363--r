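Package: bsaqtl
Title: Bulk Segregant QTL Mapping, Aneuploidy and Gene-Dosage Analysis for Yeast Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pooled-sequencing bulk segregant analysis (BSA) for
    Saccharomyces cerevisiae crosses: calls parent-heterozygous marker
    sites from multi-sample VCFs with allele-frequency and depth filters,
    scores pool pairs with an absolute log10 odds-ratio (LOD) statistic,
    calls QTL peaks with 1-LOD support intervals and intersects them
    across comparisons, detects whole-chromosome aneuploidy from
    1000-bp read-depth windows, identifies de-novo variants by parental
    subtraction, and summarizes chromosome-level expression dosage from
    RNA-seq count matrices.  Ships a meiotic cross simulator (heterozygous
    diploid parent, haploid segregants, two-locus resistance phenotypes,
    pooled read counts, coverage tracks with planted copy-number changes,
    dosage-affected expression counts) so every stage is testable without
    raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
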