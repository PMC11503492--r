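Package: delscreen
Title: Activity-Based DNA-Encoded Library Droplet Screen Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational machinery for activity-based DNA-encoded library
    (DEL) screening in droplet microfluidics: combinatorial library
    enumeration from building-block tables with physicochemical filtering,
    DNA codon (barcode) scheme construction with Hamming-distance
    guarantees, a droplet-screen simulator with Poisson bead occupancy and
    Gaussian reporter fluorescence, dynamic 5-sigma hit sorting with robust
    rolling statistics and Z-prime assay quality, sequencing-based hit
    deconvolution into per-structure k-class counts, a sampled-null false
    discovery matrix, and building-block enrichment analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
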