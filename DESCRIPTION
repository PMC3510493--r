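Package: srnascreen
Title: Accessibility-Aware Small RNA Target Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Expression-guided screening for targets of bacterial and
    archaeal small regulatory RNAs (sRNAs). Implements a McCaskill-style
    partition function over locally folded secondary structures to obtain
    unpaired probabilities (accessibility) and opening energies, a
    seed-constrained intermolecular duplex dynamic program for sRNA-mRNA
    hybridization, an anti-Shine-Dalgarno scan for ribosome binding sites,
    positional repression and RBS-accessibility activation filters keyed to
    start-codon-relative coordinates, cis-antisense overlap classification,
    delta-delta-Ct fold-change computation, and a seeded synthetic-data
    generator with planted interaction sites for end-to-end validation.
    Brute-force structure and duplex enumerators are included as independent
    oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
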