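Package: kmergcn
Title: Predicting Nanopore Kmer Ionic Currents from Nucleotide Chemical
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph convolutional regression of nanopore sequencing kmer
    characteristic ionic currents (pA) from nucleotide chemical structures.
    Assembles kmer SMILES strings from per-nucleotide building blocks,
    parses them into molecular graphs, computes atom feature matrices, and
    fits a graph-convolutional network with a 1-D convolutional stack and a
    dense head. Includes the train/test partition designs used to study
    kmer-level generalization (random downsample, base dropout, position
    dropout, base-dropout combination, modification imputation, and de novo
    prediction of modified kmers such as 5-methylcytosine), readers and
    writers for kmer-model tables and nanopolish eventalign event tables,
    an empirical kmer-model builder, atom-embedding similarity analysis,
    and a synthetic kmer-model generator with known ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
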