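# Standard valences used for implicit-hydrogen bookkeeping (neutral,
# charge-free molecules only).
.STD_VALENCE <- c(C = 4, N = 3, O = 2, P = 5)

#' Per-atom chemical feature matrix
#'
#' Computes the eight atom features used as GCN node attributes, one row per
#' atom, in order: carbon / nitrogen / oxygen / phosphorus one-hot flags,
#' atom degree (number of covalently bonded neighbours; a double bond counts
#' once), implicit valence (standard valence minus the valence accounted for
#' by the drawn bonds), total hydrogen count, and an aromaticity flag.
#' Hydrogens are implicit throughout, so the hydrogen count equals the
#' implicit valence.
#'
#' Aromaticity is perceived on the kekulized structure: a ring is aromatic
#' when every ring atom is conjugation-capable, i.e. participates in at least
#' one double bond or is a lone-pair-donating N or O that is not saturated
#' sp3-bonded carbonless... see Details.
#'
#' @details A ring (simple cycle of the molecular graph) is flagged aromatic
#' when each of its atoms either is incident to a double bond (in or out of
#' the ring) or is a nitrogen (pyrrole-type lone-pair donor). This
#' domain-restricted rule reproduces standard aromaticity perception on all
#' nucleotide building blocks: the fused purine and the pyrimidine(-one)
#' rings perceive as aromatic, the furanose sugar ring (sp3 carbons) does
#' not, and exocyclic carbonyl oxygens, amine nitrogens and methyl carbons
#' are non-aromatic.
#'
#' @param graph A `mol_graph` from [parse_smiles()] or [kmer_graph()].
#' @return Numeric matrix, n_atoms x 8, with column names
#'   `C`, `N`, `O`, `P`, `degree`, `implicit_valence`, `n_hydrogen`,
#'   `aromatic`.
#' @export
atom_features <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  el <- graph$element
  bad <- setdiff(unique(el), names(.STD_VALENCE))
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  n <- length(el)
  deg <- tabulate(c(graph$bonds[, "i"], graph$bonds[, "j"]), nbins = n)
  bond_val <- numeric(n)
  for (r in seq_len(nrow(graph$bonds))) {
    o <- graph$bonds[r, "order"]
    bond_val[graph$bonds[r, "i"]] <- bond_val[graph$bonds[r, "i"]] + o
    bond_val[graph$bonds[r, "j"]] <- bond_val[graph$bonds[r, "j"]] + o
  }
  impl <- .STD_VALENCE[el] - bond_val
  if (any(impl < 0))
    stop("negative implicit valence; bond orders exceed standard valence")
  arom <- aromatic_atoms(graph)
  X <- cbind(C = as.numeric(el == "C"), N = as.numeric(el == "N"),
             O = as.numeric(el == "O"), P = as.numeric(el == "P"),
             degree = as.numeric(deg),
             implicit_valence = as.numeric(impl),
             n_hydrogen = as.numeric(impl),
             aromatic = as.numeric(arom))
  rownames(X) <- NULL
  X
}

# logical vector: atom sits in an aromatic ring (see atom_features Details)
aromatic_atoms <- function(graph) {
  n <- length(graph$element)
  has_double <- logical(n)
  dbl <- graph$bonds[graph$bonds[, "order"] == 2, , drop = FALSE]
  has_double[c(dbl[, "i"], dbl[, "j"])] <- TRUE
  capable <- has_double | graph$element == "N"
  out <- logical(n)
  for (ring in find_rings(graph)) {
    if (all(capable[ring])) out[ring] <- TRUE
  }
  out
}

# simple cycles via the cycle space of a spanning forest: each non-tree edge
# closes exactly one fundamental cycle. Sufficient for these molecules,
# where rings share at most one edge (the purine fusion bond is a tree
# choice issue avoided by taking, per non-tree edge, the unique tree path).
find_rings <- function(graph) {
  n <- length(graph$element)
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$bonds))) {
    i <- graph$bonds[r, "i"]; j <- graph$bonds[r, "j"]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  visited <- logical(n)
  extra <- NULL  # non-tree edges
  for (root in seq_len(n)) {
    if (visited[root]) next
    depth[root] <- 0L
    visited[root] <- TRUE
    queue <- root
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          depth[w] <- depth[v] + 1L
          queue <- c(queue, w)
        } else if (w != parent[v] && v < w) {
          extra <- rbind(extra, c(v, w))
        }
      }
    }
  }
  rings <- list()
  if (!is.null(extra)) {
    for (r in seq_len(nrow(extra))) {
      a <- extra[r, 1]; b <- extra[r, 2]
      pa <- a; pb <- b
      patha <- a; pathb <- b
      while (depth[pa] > depth[pb]) { pa <- parent[pa]; patha <- c(patha, pa) }
      while (depth[pb] > depth[pa]) { pb <- parent[pb]; pathb <- c(pathb, pb) }
      while (pa != pb) {
        pa <- parent[pa]; patha <- c(patha, pa)
        pb <- parent[pb]; pathb <- c(pathb, pb)
      }
      rings[[length(rings) + 1L]] <- unique(c(patha, rev(pathb)))
    }
  }
  rings
}

#' Padding size for fixed-shape graph tensors
#'
#' The adjacency and feature matrices of all kmers are zero-padded to a
#' common size P, the maximum heavy-atom count over every kmer of length `k`
#' in the union of the given alphabets. Because atom counts are additive
#' over positions, this equals `k * max(per-base atom count) + 1` within each
#' alphabet. For canonical-plus-5mC/6mA DNA 6mers P = 133; for
#' canonical-plus-6mA RNA 5mers P = 116.
#'
#' @param alphabets An [alphabet()] or list of alphabets (uniform
#'   nucleic-acid type).
#' @param k Kmer length.
#' @return Integer padding size P.
#' @examples
#' padding_size(list(alpha_dna(), alpha_dna("5mC"), alpha_dna("6mA")), 6) # 133
#' @export
padding_size <- function(alphabets, k) {
  if (inherits(alphabets, "alphabet")) alphabets <- list(alphabets)
  if (length(alphabets) == 0) stop("empty alphabet set")
  types <- unique(vapply(alphabets, function(a) a$nucleic_type, ""))
  if (length(types) > 1) stop("alphabets mix nucleic-acid types")
  per_base_max <- max(vapply(alphabets, function(a)
    max(vapply(a$bases, function(b)
      length(parsed_fragment(b, types)$element), 0L)), 0L))
  as.integer(k * per_base_max + 1L)
}

#' Padded adjacency and feature tensors for one molecular graph
#'
#' Converts a molecular graph into the fixed-size binary adjacency matrix
#' `A` (P x P; 1 for any covalent bond regardless of order, zero diagonal)
#' and feature matrix `X` (P x 8), both zero-padded at the end of their rows
#' (and columns, for `A`).
#'
#' @param graph A `mol_graph`.
#' @param P Padding size, at least the atom count.
#' @return A list of class `padded_graph` with `A`, `X`, `n_real`.
#' @export
to_padded_tensors <- function(graph, P) {
  n <- length(graph$element)
  if (P < n)
    stop("padding overflow: graph has ", n, " atoms but P = ", P)
  A <- matrix(0, P, P)
  A[graph$bonds[, c("i", "j")]] <- 1
  A[graph$bonds[, c("j", "i")]] <- 1
  X <- matrix(0, P, 8)
  X[seq_len(n), ] <- atom_features(graph)
  colnames(X) <- c("C", "N", "O", "P", "degree", "implicit_valence",
                   "n_hydrogen", "aromatic")
  structure(list(A = A, X = X, n_real = n), class = "padded_graph")
}

#' Encode kmers as padded graph tensors
#'
#' Batch encoder used by the model: for each kmer it builds the molecular
#' graph, the normalized adjacency operator (sparse), and the feature
#' matrix, all padded to size P.
#'
#' @param kmers Character vector of kmer strings.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param P Padding size (e.g. from [padding_size()]).
#' @return A list of class `kmer_tensors` with fields `Ahat` (list of sparse
#'   P x P normalized adjacency matrices), `X` (list of P x 8 feature
#'   matrices), `n_real` (integer vector), `kmers`, `P`.
#' @export
encode_kmers <- function(kmers, nucleic_type, P) {
  graphs <- lapply(kmers, kmer_graph, nucleic_type = nucleic_type)
  n_real <- vapply(graphs, function(g) length(g$element), 0L)
  if (any(n_real > P))
    stop("padding overflow for kmer(s): ",
         paste(kmers[n_real > P], collapse = ", "))
  tens <- lapply(graphs, to_padded_tensors, P = P)
  Ahat <- lapply(tens, function(t)
    Matrix::Matrix(normalize_adjacency(t$A), sparse = TRUE))
  structure(list(Ahat = Ahat, X = lapply(tens, `[[`, "X"),
                 n_real = n_real, kmers = kmers, P = as.integer(P)),
            class = "kmer_tensors")
}
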