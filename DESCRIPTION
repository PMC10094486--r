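Package: polyhex
Title: Homoeologous Exchange and Aneuploidy Analysis for Segmental Allotetraploids
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for karyotyping and homoeologous-exchange (HE) analysis of
    segmental allotetraploids from homoeolog-specific read counts. Implements
    control-based site bias filtering, read-depth painting in 1 Mb windows with
    rung-based aneuploidy calling, G-test dosage genotyping of 10-SNP bins
    against the five homoeologous ratios (0:4 to 4:0), fragment segmentation
    and HE breakpoint-region calling, genomic feature and transposable-element
    summaries (including TE insertion polymorphism classification), Marey-map
    local recombination-rate estimation, and the association statistics that
    compare HE frequency with genomic features at chromosome and window scale.
    A fully parameterised synthetic-data generator with exported ground truth
    allows the whole pipeline to be exercised and validated without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
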