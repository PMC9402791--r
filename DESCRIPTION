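Package: trirep
Title: Trilineage T Cell Receptor Beta Repertoire Simulation, Denoising
    and Sharing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for bulk T cell receptor beta (TCRb) CDR3 amplicon
    repertoire analysis across leukocyte lineages: a V(D)J rearrangement
    and paired-end amplicon read simulator with clonal abundance skew,
    PCR/sequencing error and chimera models; overlap-based paired-end
    read merging; germline V/J assignment with conserved-motif CDR3
    junction extraction and junction decomposition; a five-checkpoint
    artifact filter cascade (sequencing-error, mosaic, amplification-
    performance, reference-sequence and frequency-threshold filters);
    per-repertoire diversity and composition statistics; multi-sample
    sharing analyses (exclusive, public/private, trilineage-common,
    turnover); and a V-J positioned diversity spot plot rendered as SVG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
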