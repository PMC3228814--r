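Package: ab454
Title: Error Profiling and Frameshift Correction for 454 Antibody Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based characterization and correction of pyrosequencing
    errors in antibody variable-domain (FV) amplicon reads. Simulates 454-style
    reads from annotated antibody references with a configurable error mixture
    dominated by single-base insertions at short homopolymer runs, aligns reads
    to their known references with BLAST-like scoring, extracts left-normalized
    insertion/deletion/substitution events with homopolymer context and V-region
    assignment, classifies reads into accurate/erroneous categories, computes
    nucleotide composition-difference signatures and recurrence tables, excises
    insertions and pads deletions to restore the reading frame, and calls
    productive/unproductive/stop-codon functionality before and after correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
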