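test_that("the SMILES parser handles atoms, branches, rings and bond orders", {
  g <- parse_smiles("OP(=O)(O)O")
  expect_identical(g$element, c("O", "P", "O", "O", "O"))
  expect_identical(nrow(g$bonds), 4L)
  expect_identical(sum(g$bonds[, "order"] == 2), 1L)
  # all phosphate bonds attach to the P atom
  expect_true(all(g$bonds[, "i"] == 2 | g$bonds[, "j"] == 2))
  ring <- parse_smiles("C1CCC1")
  expect_identical(nrow(ring$bonds), 4L)  # closure adds the 4th bond
  expect_error(parse_smiles("C1CC"), "ring closure")
  expect_error(parse_smiles("C(CC"), "unmatched")
  expect_error(parse_smiles("CC)"), "unmatched")
  expect_error(parse_smiles("CSi"), "unsupported")
})

test_that("building-block atom counts match the independent parser", {
  for (nt in c("DNA", "RNA")) {
    for (b in names(FRAG_ATOMS[[nt]])) {
      g <- parse_smiles(nucleotide_smiles(b, nt))
      expect_identical(length(g$element), unname(FRAG_ATOMS[[nt]][b]),
                       label = paste(nt, b, "atom count"))
    }
  }
})

test_that("kmer SMILES assembly concatenates blocks and appends the hydroxyl O", {
  s <- assemble_smiles("C", "DNA")
  expect_identical(s, paste0(nucleotide_smiles("C", "DNA"), "O"))
  s2 <- assemble_smiles("AT", "DNA")
  expect_identical(s2, paste0(nucleotide_smiles("A", "DNA"),
                              nucleotide_smiles("T", "DNA"), "O"))
  expect_error(assemble_smiles("", "DNA"), "empty")
  expect_error(assemble_smiles("AXA", "DNA"), "unknown base")
  expect_error(nucleotide_smiles("5mC", "RNA"), "no SMILES building block")
})

test_that("fragment-cached kmer graphs equal full-string parses", {
  for (km in c("CGACGT", "GT[5mC]AGA", "A", "TTTTTT")) {
    gf <- kmer_graph(km, "DNA")
    gp <- parse_smiles(assemble_smiles(km, "DNA"))
    expect_identical(gf$element, gp$element)
    ord <- function(b) b[order(b[, 1], b[, 2]), ]
    expect_identical(ord(gf$bonds), ord(gp$bonds))
  }
  g <- kmer_graph("AUGCU", "RNA")
  expect_identical(length(g$element), kmer_atom_count("AUGCU", "RNA"))
})

test_that("atom counts are additive over positions plus the terminal O", {
  set.seed(1)
  for (nt in c("DNA", "RNA")) {
    bases <- names(FRAG_ATOMS[[nt]])
    for (rep in 1:5) {
      sym <- sample(bases, 4, replace = TRUE)
      expect_identical(kmer_atom_count(sym, nt),
                       sum(FRAG_ATOMS[[nt]][sym]) + 1L)
    }
  }
})

test_that("aromatic atoms are exactly the frozen nucleobase-ring sets", {
  for (nt in c("DNA", "RNA")) {
    for (b in names(FRAG_AROMATIC[[nt]])) {
      g <- parse_smiles(nucleotide_smiles(b, nt))
      X <- atom_features(g)
      expect_identical(which(X[, "aromatic"] == 1) - 1L,
                       as.integer(FRAG_AROMATIC[[nt]][[b]]),
                       label = paste(nt, b, "aromatic set"))
    }
  }
})

test_that("cytidine features reproduce the independent featurizer", {
  X <- atom_features(parse_smiles(nucleotide_smiles("C", "DNA")))
  expect_identical(dim(X), c(19L, 8L))
  el_onehot <- c("C", "N", "O", "P")[apply(X[, 1:4], 1, which.max)]
  expect_identical(el_onehot, DNA_C_REF$element)
  expect_equal(unname(X[, "degree"]), DNA_C_REF$degree)
  expect_equal(unname(X[, "n_hydrogen"]), DNA_C_REF$n_h)
  expect_equal(unname(X[, "implicit_valence"]), DNA_C_REF$n_h)
  expect_equal(unname(X[, "aromatic"]), DNA_C_REF$aromatic)
  expect_true(all(rowSums(X[, 1:4]) == 1))  # one-hot exactly
  expect_true(all(X >= 0))
})

test_that("adjacency row sums equal the degree feature for every block", {
  for (nt in c("DNA", "RNA")) {
    for (b in names(FRAG_ATOMS[[nt]])) {
      g <- parse_smiles(nucleotide_smiles(b, nt))
      tens <- to_padded_tensors(g, length(g$element))
      expect_equal(unname(rowSums(tens$A)), unname(tens$X[, "degree"]),
                   label = paste(nt, b, "degree consistency"))
    }
  }
})

test_that("padding sizes reproduce the fixed tensor dimensions", {
  expect_identical(padding_size(list(alpha_dna(), alpha_dna("5mC"),
                                     alpha_dna("6mA")), 6), 133L)
  expect_identical(padding_size(list(alpha_rna(), alpha_rna("6mA")), 5), 116L)
  # a 6-letter alphabet containing 2mG admits an all-2mG 5mer: 5*24 + 1
  expect_identical(padding_size(alpha_rna(c("6mA", "2mG")), 5), 121L)
  expect_error(padding_size(list(alpha_dna(), alpha_rna()), 5), "mix")
})

test_that("padded tensors are symmetric, zero-padded, and sized P x 8", {
  g <- kmer_graph("CGACGT", "DNA")
  tens <- to_padded_tensors(g, 133)
  expect_identical(dim(tens$A), c(133L, 133L))
  expect_identical(dim(tens$X), c(133L, 8L))
  expect_identical(tens$n_real, 124L)
  expect_identical(tens$A, t(tens$A))
  expect_true(all(diag(tens$A) == 0))
  pad <- 125:133
  expect_true(all(tens$A[pad, ] == 0) && all(tens$A[, pad] == 0))
  expect_true(all(tens$X[pad, ] == 0))
  expect_true(all(tens$X >= 0))
  expect_error(to_padded_tensors(g, 100), "overflow")
})
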