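Package: TranscriptAdvisor
Title: Parameter Advising for Reference-Based Transcript Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Input-specific parameter selection for reference-based
    transcript assemblers. Candidate assemblies produced under different
    parameter vectors are scored against a reference transcriptome with a
    scaled area under the sensitivity-precision curve swept over
    per-transcript coverage thresholds; the advisor returns the assembly
    that maximizes this estimator. Advisor sets of parameter vectors are
    learned by greedy coordinate ascent from the assembler's defaults on
    training samples, and compact subsets are chosen by greedy or
    exhaustive selection on a training AUC matrix. Includes adapters for
    Scallop and StringTie, a fully deterministic mock assembler with a
    planted parameter optimum for testing and experiments, and generators
    for synthetic reference transcriptomes and assemblies.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
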