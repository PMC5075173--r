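Package: ipcalc
Title: Protein and Peptide Isoelectric Point Calculation, Benchmarking and
    pKa-Set Optimization
Version: 0.1.0
Authors@R:
    person("ipcalc", "developers", email = "ipcalc@example.org",
           role = c("aut", "cre"))
Description: Computes the net charge and isoelectric point (pI) of proteins
    and peptides from their amino-acid sequence with the Henderson-Hasselbalch
    charge model, under any of 17 published pKa parameter sets or user-supplied
    ones. Includes the full benchmarking toolkit used to compare pKa sets
    against experimentally measured pI values (RMSD, percent difference,
    outlier counts, per-record consensus), a curation pipeline for
    pI-annotated FASTA datasets (replicate averaging, MSE-based outlier
    removal, near-identity redundancy clustering, train/test splitting),
    a basin-hopping optimizer that derives new pKa sets from labeled data
    under nested 10-fold cross-validation, a synthetic fixture generator so
    every component is testable without external downloads, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
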