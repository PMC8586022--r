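#' Atom embeddings from the final GCN layer
#'
#' Runs a kmer through the trained GCN stack (dropout disabled) and returns
#' the final-layer activation vectors of the real (non-padded) atoms. These
#' per-atom feature vectors summarize each atom's chemical context within the
#' graph distance reached by the stacked layers, and underlie the atom-level
#' similarity analysis.
#'
#' @param model A trained `gcn_model`.
#' @param kmer A kmer string.
#' @return An `atom_embedding`: matrix of `n_real` rows x final-GCN-width
#'   columns, with a `labels` attribute (data.frame: `atom` 0-based index,
#'   `element`, `nucleotide_position`).
#' @export
atom_embeddings <- function(model, kmer) {
  stopifnot(inherits(model, "gcn_model"))
  nt <- model$config$nucleic_type
  graph <- kmer_graph(kmer, nt)
  tens <- encode_kmers(kmer, nt, model$P)
  H <- tens$X[[1]]
  Ahat <- tens$Ahat[[1]]
  for (l in seq_along(model$params$Wg))
    H <- elu(as.matrix(Ahat %*% H) %*% model$params$Wg[[l]])
  n <- tens$n_real[1]
  emb <- H[seq_len(n), , drop = FALSE]
  sym <- drop(kmer_symbols(kmer))
  sizes <- vapply(sym, function(s)
    length(parsed_fragment(s, nt)$element), 0L)
  nuc_pos <- c(rep(seq_along(sym), sizes), length(sym))  # terminal O
  attr(emb, "labels") <- data.frame(atom = 0:(n - 1),
                                    element = graph$element,
                                    nucleotide_position = nuc_pos)
  attr(emb, "kmer") <- if (length(kmer) == 1) kmer else
    symbols_to_kmer(kmer)
  class(emb) <- c("atom_embedding", class(emb))
  emb
}

#' Atom-atom similarity matrix
#'
#' Pearson correlation between atom embedding rows, within one kmer or
#' across two kmers encoded by the same model. Atoms whose embedding has
#' zero variance get sentinel entries of 0 (1 on the self diagonal) and are
#' listed in the `zero_variance` attribute instead of propagating NaN.
#'
#' @param e1 An [atom_embeddings()] matrix.
#' @param e2 Optional second embedding (cross-kmer similarity); must come
#'   from the same model (equal width).
#' @return A `similarity_matrix`: n1 x n2 matrix of Pearson r values with
#'   atom labels as dimnames; symmetric with unit diagonal when `e2` is
#'   absent.
#' @export
atom_similarity <- function(e1, e2 = NULL) {
  cross <- !is.null(e2)
  if (!cross) e2 <- e1
  if (ncol(e1) != ncol(e2))
    stop("embeddings have different widths (different models?)")
  zv1 <- apply(e1, 1, stats::sd) == 0
  zv2 <- apply(e2, 1, stats::sd) == 0
  S <- suppressWarnings(stats::cor(t(e1), t(e2)))
  S[zv1, ] <- 0
  S[, zv2] <- 0
  if (!cross) {
    S[cbind(which(zv1), which(zv1))] <- 1
    S <- (S + t(S)) / 2   # enforce exact symmetry against rounding
    diag(S) <- 1
  }
  lab <- function(e) paste0(attr(e, "labels")$atom, ":",
                            attr(e, "labels")$element)
  dimnames(S) <- list(lab(e1), lab(e2))
  attr(S, "zero_variance") <- list(rows = which(zv1), cols = which(zv2))
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Project atom embeddings to two dimensions
#'
#' Projects the pooled atom embedding rows of one or more kmers onto two
#' dimensions for visualization. Principal components (the default) give a
#' deterministic linear projection; classical multidimensional scaling on
#' Euclidean distances is also available. Coordinates only summarize the
#' atom-level similarity structure; cluster shapes are not comparable across
#' methods.
#'
#' @param embeddings One [atom_embeddings()] matrix or a list of them.
#' @param seed Integer seed (kept for interface stability; both methods are
#'   deterministic).
#' @param method `"pca"` or `"mds"`.
#' @return Data frame with columns `dim1`, `dim2` plus the atom label
#'   columns, one row per atom across all inputs.
#' @export
project_2d <- function(embeddings, seed = 1L, method = c("pca", "mds")) {
  method <- match.arg(method)
  if (!is.list(embeddings)) embeddings <- list(embeddings)
  mats <- lapply(embeddings, unclass)
  M <- do.call(rbind, mats)
  if (nrow(M) < 2) stop("need at least 2 atoms to project")
  labels <- do.call(rbind, lapply(seq_along(embeddings), function(i) {
    lb <- attr(embeddings[[i]], "labels")
    lb$kmer <- attr(embeddings[[i]], "kmer")
    lb
  }))
  coords <- local_seed(seed, {
    if (method == "pca") {
      p <- stats::prcomp(M, rank. = 2, center = TRUE, scale. = FALSE)
      xy <- p$x
      if (ncol(xy) < 2) xy <- cbind(xy, 0)
      xy
    } else {
      stats::cmdscale(stats::dist(M), k = 2)
    }
  })
  out <- data.frame(dim1 = coords[, 1], dim2 = coords[, 2])
  cbind(out, labels)
}
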