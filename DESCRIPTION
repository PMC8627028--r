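Package: asmqual
Title: Reference-Free Genome Assembly Quality Scoring from Read Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores genome assemblies without a reference genome. Computes a
    suite of contiguity, completeness and accuracy metrics from an assembly
    (FASTA) plus mapped paired-end reads (FASTQ or SAM/BAM), and applies a
    regression model, trained against reference-based quality scores, to
    collapse the metrics into a single comparable quality score per assembly
    or chromosome. Includes the reference-based scoring and scaling scheme
    used to construct training targets (percent matching bases with internal
    and external scaling against an ideal metric vector), a feature
    selection cascade (Pearson filter, joint mutual information, permutation
    importance, exhaustive subset regression), a model zoo with
    cross-validated tuning, and simulators for degraded assemblies,
    paired-end reads and full synthetic training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    caret,
    randomForest,
    glmnet,
    kernlab,
    e1071
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
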