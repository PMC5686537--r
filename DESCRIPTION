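Package: codevolve
Title: Quantifying and Maximizing the Evolvability of Genetic Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring how readily a genetic code lets single
    nucleotide replacements (SNRs) reach alternative amino acids, and for
    designing codon tables that maximize that accessibility. Implements
    per-codon SNR accessibility metrics and a combined code fitness score,
    an edge census of the 288 Hamming-distance-1 codon pairs, minimum
    nucleotide replacement distances between amino acids, a seeded genetic
    algorithm and an exhaustive best-move search over codon reassignments,
    and a synonymous gene-recoding procedure that preserves the encoded
    protein while tracking mRNA folding energy and secondary structure.
    Includes generators for synthetic genes, scrambled codes and
    substitution-count tables so every stage can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
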