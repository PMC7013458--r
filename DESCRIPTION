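Package: methyledit
Title: Specificity Analysis of dCas9-SunTag/DNMT3A-DNMT3L Targeted DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the efficiency and specificity of CRISPR/dCas9
    directed DNA methylation (epigenome editing). Implements targeted
    bisulfite-amplicon analysis (quality trimming, pair merging,
    bisulfite-aware ungapped alignment, per-CpG methylation calling and
    conversion-rate QC), MBD-seq style genome-wide off-target quantification
    with binned RPKM coverage and an internal top-K stably-methylated-CGI
    re-calibration, differential peak calling and CpG-island classification,
    an sgRNA off-target scanner (NGG PAM, bounded Hamming mismatches), and
    on/off-target specificity metrics. A seeded synthetic-data generator
    produces genomes, methylomes, bisulfite amplicon reads and MBD-enriched
    fragment sets with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
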