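Package: fscmine
Title: Mining Frequent Co-Splicing Clusters Across Weighted Exon Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies frequent co-splicing clusters: sets of cassette exons
    that form heavy subgraphs recurrently across many weighted co-splicing
    networks. Each RNA-seq dataset is summarised as a network whose nodes are
    exons and whose edge weights are Pearson correlations between exon
    inclusion-rate profiles; the collection of networks is stacked into a
    third-order tensor and heavy recurrent subtensors are located by
    maximising a heaviness objective over nonnegative exon and network
    membership vectors under mixed Lp-norm constraints, solved by multi-stage
    convex relaxation. Includes inclusion-rate computation from
    transcript-level abundance tables, a planted-cluster simulation benchmark,
    and hypergeometric gene-set enrichment with random size-matched baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
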