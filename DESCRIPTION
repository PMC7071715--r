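Package: bhlhtools
Title: Genome-Wide Mining and Characterization of bHLH Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for mining basic/helix-loop-helix
    (bHLH) transcription factor families from a proteome and characterizing
    them: profile-scoring-matrix domain discovery mapped onto the canonical
    60-position bHLH coordinate system, DNA-binding-category classification
    (G-box, non-G-box, non-E-box, non-DNA-binding), per-position consensus
    conservation profiling, ortholog-based family naming with decimal
    suffixes, neighbor-joining phylogeny with bootstrap support and
    subfamily label inheritance, tandem and collinear gene duplication
    detection from gene coordinates and homology, and iron-deficiency
    candidate prioritization combining expression filters, GO-set
    intersection and 2^-ddCt qPCR time-course analysis. A synthetic-data
    generator plants domains, duplications, expression structure and qPCR
    fold changes with a ground-truth manifest so every stage is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
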