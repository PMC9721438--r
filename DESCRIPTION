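Package: protiso
Title: Long-Read Proteogenomics: Protein Isoform Databases and Peptide Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating long-read transcript models with bottom-up
    mass-spectrometry proteomics. Builds a reference catalog from a GTF
    annotation, genome and protein FASTA plus APPRIS principal-isoform labels;
    classifies observed long-read transcripts against the reference (FSM, NIC,
    NNC) with full-length-read CPM abundances; calls the most plausible open
    reading frame per transcript; classifies predicted proteins (pFSM, pNIC,
    pNNC); assembles a sample-specific hybrid protein search database; and maps
    externally identified peptides onto that database to derive tiered isoform
    evidence, abundance-based isoform nominations and novel-peptide calls. A
    ground-truthed synthetic data generator makes the whole pipeline testable
    without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
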