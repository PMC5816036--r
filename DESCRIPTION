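Package: catraits
Title: Community-Aggregated Trait Analysis of Predicted Functional Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Downstream analysis of predicted functional (KEGG ortholog)
    count tables from community profiling. Identifies KEGG orthologs (KOs)
    differentially enriched between treatment groups with a self-contained
    negative-binomial Wald test using median-of-ratios normalization, calls
    enriched and depleted KEGG pathways against a subset-resampling
    (bootstrap percentile) null, screens out pathways under-represented in
    the predicted metagenome, classifies pathway calls into Grime's
    Competitor/Stress-tolerator/Ruderal (CSR) life-strategy classes via a
    packaged trait registry, and computes per-treatment CSR net-change
    scores. Includes a synthetic-data generator with planted pathway-level
    effects so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
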