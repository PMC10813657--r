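Package: difcir
Title: Differential Genic Profiling of Cell-Free Extrachromosomal Circular DNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies per-gene production of extrachromosomal circular DNA
    (eccDNA) from split-read circle tables and calls differentially produced
    per-gene eccDNAs (DPpGCs) between sample groups with the DifCir procedure.
    Includes breakpoint-jitter coalescing of circle calls, length-scaled
    log2-equalized produced-per-gene-circle (PpGC) matrices, a pooled-variance
    differential test with fold-change and significance thresholds,
    chromosome-landscape enrichment with hypergeometric mid-p-values,
    chromosomal-fragile-site, GWAS and gene-set over-representation
    annotation, cross-species profile intersection, and a seeded synthetic
    cohort generator with planted effect genes for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
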