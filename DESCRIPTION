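Package: symmeth
Title: Differential DNA Methylation and Its Integration with Gene
    Expression in Bacterial Symbiosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-wide integration of single-molecule (SMRT) DNA
    methylation calls with differential gene expression between the
    free-living and endosymbiotic (bacteroid) states of a nitrogen-fixing
    bacterium. Enumerates strand-specific methylatable sites of degenerate
    IUPAC motifs (including bipartite spacer motifs), parses PacBio-style
    base-modification GFF files with coverage/modQV quality control,
    compares per-site methylation states between two conditions, computes
    per-motif summaries, regional (symbiosis-island, coding vs. upstream)
    tallies and sliding-window methylome profiles, performs per-gene
    differential expression with Benjamini-Hochberg control, and joins
    methylation and expression changes into candidate-gene lists. A
    fully specified synthetic-data generator provides ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
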