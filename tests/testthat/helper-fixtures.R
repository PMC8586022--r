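# Shared fixtures: frozen reference values and small builders.

# Heavy-atom counts of the nucleotide building blocks, frozen from an
# independent cheminformatics toolkit parse of the same SMILES strings.
FRAG_ATOMS <- list(
  DNA = c(A = 21L, T = 20L, C = 19L, G = 22L, `5mC` = 20L, `6mA` = 22L),
  RNA = c(A = 22L, U = 20L, C = 20L, G = 23L, `6mA` = 23L, `2mG` = 24L)
)

# 0-based indices of aromatic atoms per building block, frozen from the same
# independent aromaticity perception (exactly the nucleobase ring atoms).
FRAG_AROMATIC <- list(
  DNA = list(A = c(9:13, 15:18), T = c(9, 10, 12, 13, 15, 17),
             C = c(9, 10, 12, 13, 15, 16), G = c(9:15, 17, 18),
             `5mC` = c(9, 10, 12, 13, 15, 17),
             `6mA` = c(9:13, 16:19)),
  RNA = list(A = c(9:13, 15:18), U = c(9, 10, 12, 13, 15, 16),
             C = c(9, 10, 12, 13, 15, 16), G = c(9:15, 17, 18),
             `6mA` = c(9:13, 16:19), `2mG` = c(9:15, 18, 19))
)

# full frozen feature reference for the DNA cytidine block:
# element, degree, hydrogen count, aromatic flag per atom (0-based order)
DNA_C_REF <- data.frame(
  element = c("O","P","O","O","O","C","C","O","C","N","C","O","N","C","N",
              "C","C","C","C"),
  degree  = c(1,4,1,1,2,2,3,2,3,3,3,1,2,3,1,2,2,2,2),
  n_h     = c(1,0,0,1,0,2,1,0,1,0,0,0,0,0,2,1,1,2,2),
  aromatic = c(0,0,0,0,0,0,0,0,0,1,1,0,1,1,0,1,1,0,0)
)

# micro network for fast tests: 1 GCN layer, 1 CNN layer, small everything
micro_config <- function(nucleic_type = "DNA") {
  gcn_config(1, 1, 2, 16, nucleic_type)
}

micro_tc <- function(epochs = 3, seed = 1) {
  train_config(max_epochs = epochs, batch_size = 8, seed = seed)
}

# brute-force reference for one graph-convolution step: per-atom loop over
# the self-augmented neighbourhood with symmetric degree normalization
gcn_oracle <- function(A, H, W) {
  n <- nrow(A)
  At <- A + diag(n)
  deg <- rowSums(At)
  M <- matrix(0, n, ncol(H))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (At[i, j] != 0)
        M[i, ] <- M[i, ] + H[j, ] / sqrt(deg[i] * deg[j])
    }
  }
  Z <- M %*% W
  ifelse(Z > 0, Z, exp(Z) - 1)
}

# random symmetric adjacency on n atoms (connected not required)
random_adjacency <- function(n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
  A
}

# write a synthetic eventalign TSV; returns the path
write_eventalign_fixture <- function(path, kmers, means, n_placeholder = 0,
                                     shuffle_cols = FALSE) {
  n <- length(kmers)
  tab <- data.frame(
    contig = "ref1", position = seq_len(n) - 1L, reference_kmer = kmers,
    read_index = 0L, strand = "t", event_index = seq_len(n) - 1L,
    event_level_mean = means, event_stdv = 1.5, event_length = 0.003,
    model_kmer = kmers, model_mean = means, model_stdv = 1.8,
    stringsAsFactors = FALSE)
  if (n_placeholder > 0) {
    ph <- tab[rep(1, n_placeholder), ]
    ph$model_kmer <- strrep("N", nchar(kmers[1]))
    tab <- rbind(tab, ph)
  }
  if (shuffle_cols) tab <- tab[, sample(ncol(tab))]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
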