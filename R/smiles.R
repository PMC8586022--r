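# Per-nucleotide SMILES building blocks. Each string encodes a
# 5'-phosphorylated (deoxy)ribonucleotide written so that plain concatenation
# chains nucleotides through the phosphodiester backbone: the final sugar
# carbon of one block bonds to the leading phosphate oxygen of the next.
# Ring-closure digits are local to each block, so concatenation is safe.
.NUC_SMILES <- list(
  DNA = c(
    A     = "OP(=O)(O)OCC1OC(N3C=NC2=C(N)N=CN=C23)CC1",
    T     = "OP(=O)(O)OCC1OC(N2C(=O)NC(=O)C(C)=C2)CC1",
    C     = "OP(=O)(O)OCC1OC(N2C(=O)N=C(N)C=C2)CC1",
    G     = "OP(=O)(O)OCC1OC(N2C=NC3=C2N=C(N)NC3=O)CC1",
    `5mC` = "OP(=O)(O)OCC1OC(N2C(=O)N=C(N)C(C)=C2)CC1",
    `6mA` = "OP(=O)(O)OCC1OC(N3C=NC2=C(NC)N=CN=C23)CC1"),
  RNA = c(
    A     = "OP(=O)(O)OCC1OC(N3C=NC2=C(N)N=CN=C23)C(O)C1",
    U     = "OP(=O)(O)OCC1OC(N2C(=O)NC(=O)C=C2)C(O)C1",
    C     = "OP(=O)(O)OCC1OC(N2C(=O)N=C(N)C=C2)C(O)C1",
    G     = "OP(=O)(O)OCC1OC(N2C=NC3=C2N=C(N)NC3=O)C(O)C1",
    `6mA` = "OP(=O)(O)OCC1OC(N3C=NC2=C(NC)N=CN=C23)C(O)C1",
    `2mG` = "OP(=O)(O)OCC1OC(N2C=NC3=C2N=C(NC)NC3=O)C(O)C1")
)

#' Nucleotide SMILES building blocks
#'
#' Returns the SMILES string of one nucleotide building block, or the whole
#' table for a nucleic-acid type. Lookup fails loudly for unknown
#' (base, type) pairs.
#'
#' @param base Base symbol (`A`, `T`, `U`, `C`, `G`, `5mC`, `6mA`, `2mG`), or
#'   `NULL` for the full table of the type.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return A SMILES string, or a named character vector of them.
#' @examples
#' nucleotide_smiles("C", "DNA")
#' @export
nucleotide_smiles <- function(base = NULL, nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  tab <- .NUC_SMILES[[nucleic_type]]
  if (is.null(base)) return(tab)
  if (!base %in% names(tab))
    stop("no SMILES building block for base '", base, "' (", nucleic_type, ")")
  unname(tab[base])
}

#' Assemble the SMILES string of a kmer
#'
#' Concatenates the per-nucleotide SMILES building blocks in kmer order and
#' appends a terminal `"O"` for the residual unbonded 3' hydroxyl group.
#'
#' @param kmer A kmer string (e.g. `"GT[5mC]AGA"`) or symbol vector.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return A SMILES string.
#' @examples
#' assemble_smiles("C", "DNA")
#' @export
assemble_smiles <- function(kmer, nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  sym <- if (length(kmer) == 1 && !kmer %in% .KNOWN_BASES)
    drop(kmer_symbols(kmer)) else as.character(kmer)
  if (length(sym) == 0 || !nzchar(sym[1])) stop("empty kmer")
  parts <- vapply(sym, nucleotide_smiles, "", nucleic_type = nucleic_type)
  paste0(paste(parts, collapse = ""), "O")
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the grammar used by the nucleotide building blocks: atoms
#' `C`/`N`/`O`/`P`, single and double (`=`) bonds, parenthesised branches,
#' and ring-closure digits. Atoms are indexed in order of appearance
#' (1-based in R; the conventional 0-based atom numbers are `index - 1`).
#'
#' @param smiles A SMILES string.
#' @return A `mol_graph`: list with `element` (character vector),
#'   `bonds` (integer matrix with columns `i`, `j`, `order`; `i < j`),
#'   and attribute `smiles`.
#' @examples
#' g <- parse_smiles("OP(=O)(O)O")
#' length(g$element) # 5
#' @export
parse_smiles <- function(smiles) {
  ch <- strsplit(smiles, "")[[1]]
  element <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  prev <- 0L            # current attachment atom
  stack <- integer(0)   # branch return points
  ring <- list()        # open ring closures: digit -> atom index
  pend <- 1L            # bond order for the next bond
  for (pos in seq_along(ch)) {
    c1 <- ch[pos]
    if (c1 %in% c("C", "N", "O", "P")) {
      element <- c(element, c1)
      a <- length(element)
      if (prev > 0L) {
        bi <- c(bi, prev); bj <- c(bj, a); bo <- c(bo, pend)
      }
      pend <- 1L
      prev <- a
    } else if (c1 == "=") {
      pend <- 2L
    } else if (c1 == "(") {
      if (prev == 0L) stop("branch before any atom at position ", pos)
      stack <- c(stack, prev)
    } else if (c1 == ")") {
      if (length(stack) == 0) stop("unmatched ')' at position ", pos)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("[0-9]", c1)) {
      if (prev == 0L) stop("ring closure before any atom at position ", pos)
      if (is.null(ring[[c1]])) {
        ring[[c1]] <- prev
      } else {
        bi <- c(bi, ring[[c1]]); bj <- c(bj, prev); bo <- c(bo, 1L)
        ring[[c1]] <- NULL
      }
    } else if (c1 != " ") {
      stop("unsupported SMILES token '", c1, "' at position ", pos)
    }
  }
  if (length(stack) > 0) stop("unmatched '(' in SMILES")
  if (length(ring) > 0)
    stop("unmatched ring closure digit(s): ",
         paste(names(ring), collapse = ", "))
  if (length(element) == 0) stop("SMILES contains no atoms")
  bonds <- cbind(i = pmin(bi, bj), j = pmax(bi, bj), order = bo)
  if (any(bonds[, "i"] == bonds[, "j"])) stop("self-bond in SMILES")
  structure(list(element = element, bonds = bonds),
            class = "mol_graph", smiles = smiles)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds (%d double)\n",
              length(x$element), nrow(x$bonds), sum(x$bonds[, "order"] == 2)))
  invisible(x)
}

# parsed building blocks, cached per (type, base)
.frag_cache <- new.env(parent = emptyenv())
parsed_fragment <- function(base, nucleic_type) {
  key <- paste(nucleic_type, base, sep = ":")
  if (is.null(.frag_cache[[key]]))
    .frag_cache[[key]] <- parse_smiles(nucleotide_smiles(base, nucleic_type))
  .frag_cache[[key]]
}

#' Molecular graph of a kmer
#'
#' Builds `parse_smiles(assemble_smiles(kmer))` efficiently by concatenating
#' pre-parsed nucleotide fragments: atom indices are offset per fragment,
#' consecutive nucleotides are joined by a single bond from the last atom of
#' one fragment to the first atom of the next (the phosphodiester linkage as
#' written), and the terminal hydroxyl oxygen is appended. The result is
#' identical to parsing the full assembled string.
#'
#' @inheritParams assemble_smiles
#' @return A `mol_graph`.
#' @examples
#' g <- kmer_graph("CGACGT", "DNA")
#' length(g$element) # 124
#' @export
kmer_graph <- function(kmer, nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  sym <- if (length(kmer) == 1 && !kmer %in% .KNOWN_BASES)
    drop(kmer_symbols(kmer)) else as.character(kmer)
  if (length(sym) == 0 || !nzchar(sym[1])) stop("empty kmer")
  element <- character(0)
  bonds <- NULL
  offset <- 0L
  for (s in sym) {
    fr <- parsed_fragment(s, nucleic_type)
    nb <- fr$bonds
    nb[, c("i", "j")] <- nb[, c("i", "j")] + offset
    if (offset > 0L)  # chain bond: previous fragment's last atom -> first atom
      bonds <- rbind(bonds, cbind(i = offset, j = offset + 1L, order = 1L))
    bonds <- rbind(bonds, nb)
    element <- c(element, fr$element)
    offset <- offset + length(fr$element)
  }
  element <- c(element, "O")  # residual 3' hydroxyl
  bonds <- rbind(bonds, cbind(i = offset, j = offset + 1L, order = 1L))
  structure(list(element = element, bonds = bonds), class = "mol_graph",
            smiles = assemble_smiles(sym, nucleic_type))
}

#' Heavy-atom count of a kmer
#'
#' Sum of per-nucleotide heavy-atom counts plus the terminal hydroxyl oxygen.
#'
#' @inheritParams assemble_smiles
#' @return Integer atom count.
#' @export
kmer_atom_count <- function(kmer, nucleic_type = c("DNA", "RNA")) {
  nucleic_type <- match.arg(nucleic_type)
  sym <- if (length(kmer) == 1 && !kmer %in% .KNOWN_BASES)
    drop(kmer_symbols(kmer)) else as.character(kmer)
  sum(vapply(sym, function(s)
    length(parsed_fragment(s, nucleic_type)$element), 0L)) + 1L
}
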