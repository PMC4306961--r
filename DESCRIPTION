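Package: ampcov
Title: Coverage Planning and Accuracy Assessment for Tailed-Amplicon
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing per-enzyme read accuracy in tailed-amplicon
    high-throughput sequencing experiments and for planning the coverage
    needed to recover all true alleles of a locus with a stated confidence.
    Includes an exact multinomial allele-recovery model (with a Monte Carlo
    cross-check) for single-haplotype and multi-allele loci under equal or
    biased allele amplification, a deterministic MID-barcode demultiplexer
    with completeness and size filters, identity-based read classification
    against known reference alleles, a synthetic amplicon read generator
    with controllable substitution, homopolymer-indel and chimera error
    structure, and enzyme-level coverage reports with a stratified
    permutation comparison of PCR conditions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
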