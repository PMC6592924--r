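Package: riboprobe
Title: Sample-Centric FISH Probe Design and Evaluation from Shotgun 16S
    rRNA Sequence Tags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing fluorescence in situ hybridisation (FISH)
    probes directly from shotgun metagenomic or metatranscriptomic reads,
    without recourse to a global reference database. Extracts fixed-length
    sequence tags ("ribotags", default 33 bp) from the V6 hypervariable
    region of the 16S rRNA by recognising an adjacent conserved anchor,
    tallies tags into sample-centric OTU tables, annotates them against a
    reference tag database by exact or near match with lowest-common-ancestor
    resolution, derives truncated probe candidates (default 17 bp) with
    nearest-neighbour melting-temperature advisories, evaluates probe
    coverage and specificity in silico by mismatch-tolerant search, computes
    community profiles and pre-/post-sort fold enrichment, and quantifies
    FISH microscopy via threshold segmentation, biovolume fractions,
    Manders' co-localisation coefficients and formamide dissociation-curve
    summaries. A synthetic-data module generates references, communities,
    error-bearing reads, sorted samples and toy images with known ground
    truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
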