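Package: fragcov
Title: Fragment-Size Distribution Estimation and CpG Coverage for
    Enrichment-Based Methylome Sequencing
Version: 0.1.0
Authors@R:
    person("fragcov", "developers", email = "fragcov@example.org",
           role = c("aut", "cre"))
Description: Non-parametric estimation of sample-specific DNA fragment-size
    distributions from single-end sequencing reads around isolated CpG
    sites, for enrichment-based (MBD/MeDIP) methylome-wide sequencing
    studies.  Provides the discrete probability model linking fragment
    sizes, read-start positions and CpG coverage; kernel and cubic-spline
    smoothing of read-start counts with monotone rearrangement; multi-read
    weighting and duplicate-read collapsing; genome-wide per-CpG
    fragment-coverage estimation with between-sample standardization; and
    a simulator reproducing the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    tools,
    jsonlite,
    optparse,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
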