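Package: spretrace
Title: Iterative Profile-HMM Discovery of SPRE-Like Retroviral RNA Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-step homology search pipeline for short retroviral RNA
    elements such as the syncytin post-transcriptional regulatory element
    (SPRE) in repeat-family consensus libraries and genomes. Step one finds
    exact occurrences of a short core motif (default the 17-nt SPRE core)
    in a consensus library and extracts core-anchored flanking windows;
    step two fits a nucleotide profile hidden Markov model to the windows
    and iteratively re-searches the library, realigning and rebuilding the
    model each cycle and selecting the cycle with the most hits. The fitted
    model can then scan long targets (genomes, viral sequence sets) in
    overlapping chunks with Gumbel-calibrated E-values. Downstream analytics
    cover relative position-bias scores along family consensuses,
    strand-aware directional interval extension, stranded intersection with
    RepeatMasker-style repeat annotations, per-family overlap tallies,
    LTR-class fractions, and relative synonymous codon frequencies. A
    synthetic-data module generates consensus libraries, genomes, and decoy
    sets with machine-readable ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
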