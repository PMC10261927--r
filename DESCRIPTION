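Package: isomirtools
Title: Template-Aware isomiR Classification and Uridylation Profiling for
    Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies small RNA-seq reads into isomiR classes (canonical,
    internal single-nucleotide variants, non-templated 3' additions, and 5'/3'
    length variants) with a hierarchical schema that uses the miRNA hairpin to
    separate non-templated tails from templated extensions. Provides adapter
    and UMI handling for fixed- and randomized-adapter library layouts,
    per-sample composition and substitution-spectrum summaries, per-miRNA and
    per-arm uridylation tables, differential-uridylation calling between
    wild-type and TUT4/7 double-knockout groups with a cross-study
    randomization Z-score, uridylation-aware (tail-U) target-site prediction
    over multi-species 3'-UTR sets, and a fully seeded synthetic read
    generator with per-read ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
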