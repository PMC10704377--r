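Package: bisfoot
Title: Single-Molecule Bisulfite Footprinting of Single-Stranded DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects single-stranded DNA regions (R-loops and
    G-quadruplex-displaced strands) at a locus from non-denaturing
    sodium bisulfite clone sequencing. Provides bisulfite-aware clone
    alignment, strand-of-origin assignment, per-cytosine conversion
    calling with CpG handling, conversion-stretch and footprint
    detection, per-position conversion frequency, condition comparison
    (e.g. with and without RNase H), AID deamination mutation-frequency
    analysis, WRC hotspot and conventional/extended G-quadruplex motif
    scanning (long loops and bulged G-tracts), breakpoint clustering,
    and signal-track summarisation. A fully seeded clone simulator with
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
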