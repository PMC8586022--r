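# Base symbols recognized anywhere in the package. Modified bases are
# multi-character tokens; kmers are therefore handled as symbol vectors, and
# string forms use brackets around modified symbols, e.g. "GT[5mC]AGA".
.KNOWN_BASES <- c("A", "T", "U", "C", "G", "5mC", "6mA", "2mG")
.MOD_PARENT <- c("5mC" = "C", "6mA" = "A", "2mG" = "G")

#' Nucleotide alphabet
#'
#' An alphabet is an ordered set of base symbols together with the nucleic-acid
#' type it belongs to. The base order fixes the (deterministic) lexicographic
#' kmer enumeration order. Modified bases (`5mC`, `6mA`, `2mG`) map to a
#' canonical parent base (`C`, `A`, `G`).
#'
#' @param bases Character vector of base symbols, drawn from
#'   `A, T, U, C, G, 5mC, 6mA, 2mG`. Must be unique; `T` is DNA-only and `U`
#'   RNA-only.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param name Optional identifier; defaults to a label built from the bases.
#' @return An object of class `alphabet` with fields `name`, `nucleic_type`,
#'   `bases`.
#' @examples
#' alphabet(c("A", "T", "C", "G"), "DNA")
#' alphabet(c("A", "T", "C", "G", "5mC"), "DNA")
#' @export
alphabet <- function(bases, nucleic_type = c("DNA", "RNA"), name = NULL) {
  nucleic_type <- match.arg(nucleic_type)
  bases <- as.character(bases)
  bad <- setdiff(bases, .KNOWN_BASES)
  if (length(bad) > 0)
    stop("unknown base symbol(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(bases))
    stop("alphabet bases must be unique")
  if (nucleic_type == "DNA" && "U" %in% bases)
    stop("U is only valid in RNA alphabets")
  if (nucleic_type == "RNA" && "T" %in% bases)
    stop("T is only valid in DNA alphabets")
  if (is.null(name))
    name <- paste0(tolower(nucleic_type), "_", paste(bases, collapse = ""))
  structure(list(name = name, nucleic_type = nucleic_type, bases = bases),
            class = "alphabet")
}

#' @export
print.alphabet <- function(x, ...) {
  cat("<alphabet>", x$name, paste0("(", x$nucleic_type, "):"),
      paste(x$bases, collapse = " "), "\n")
  invisible(x)
}

#' Canonical and modification-extended alphabet presets
#'
#' `alpha_dna()` is the canonical `{A, T, C, G}` DNA alphabet and `alpha_rna()`
#' the canonical `{A, U, C, G}` RNA alphabet; `mods` appends modified bases.
#'
#' @param mods Character vector of modified bases to append (e.g. `"5mC"`).
#' @return An [alphabet()].
#' @examples
#' alpha_dna("5mC")
#' alpha_rna("6mA")
#' @export
alpha_dna <- function(mods = character()) {
  alphabet(c("A", "T", "C", "G", mods), "DNA")
}

#' @rdname alpha_dna
#' @export
alpha_rna <- function(mods = character()) {
  alphabet(c("A", "U", "C", "G", mods), "RNA")
}

#' Default kmer length for a nucleic-acid type
#'
#' The pore sensing region is modelled with k = 6 for DNA and k = 5 for RNA.
#'
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @return Integer kmer length.
#' @export
default_k <- function(nucleic_type) {
  switch(match.arg(nucleic_type, c("DNA", "RNA")), DNA = 6L, RNA = 5L)
}

#' Enumerate all kmers of an alphabet
#'
#' Produces all `|bases|^k` kmers in lexicographic order over the alphabet's
#' declared base order (first position most significant). The order is
#' deterministic and stable across calls.
#'
#' @param alphabet An [alphabet()].
#' @param k Kmer length (positive integer).
#' @return Character vector of kmer strings (modified bases bracketed).
#' @examples
#' length(enumerate_kmers(alpha_dna(), 6)) # 4096
#' @export
enumerate_kmers <- function(alphabet, k) {
  stopifnot(inherits(alphabet, "alphabet"))
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  toks <- format_base(alphabet$bases)
  # build positions right-to-left so position 1 varies slowest
  out <- ""
  for (pos in seq_len(k)) {
    out <- as.vector(t(outer(out, toks, paste0)))
  }
  out
}

format_base <- function(bases) {
  ifelse(nchar(bases) > 1, paste0("[", bases, "]"), bases)
}

#' Convert kmer strings to symbol matrices and back
#'
#' Kmers are symbol sequences, never raw character strings: modified bases are
#' multi-character tokens, written in brackets (`GT[5mC]AGA`). The nanopolish
#' dialect writes 5mC as the single letter `M`.
#'
#' @param kmers Character vector of kmer strings.
#' @param dialect `"brackets"` (default) or `"nanopolish"` (`M` = 5mC).
#' @return `kmer_symbols()`: a character matrix, one row per kmer, one column
#'   per position. `symbols_to_kmer()`: a character vector of kmer strings.
#' @examples
#' kmer_symbols("GT[5mC]AGA")
#' @export
kmer_symbols <- function(kmers, dialect = c("brackets", "nanopolish")) {
  dialect <- match.arg(dialect)
  if (dialect == "nanopolish") kmers <- gsub("M", "[5mC]", kmers, fixed = TRUE)
  toks <- lapply(strsplit(kmers, ""), function(ch) {
    out <- character(0)
    i <- 1L
    n <- length(ch)
    while (i <= n) {
      if (ch[i] == "[") {
        j <- i + 1L
        while (j <= n && ch[j] != "]") j <- j + 1L
        if (j > n) stop("unterminated '[' in kmer string")
        out <- c(out, paste(ch[(i + 1L):(j - 1L)], collapse = ""))
        i <- j + 1L
      } else {
        out <- c(out, ch[i])
        i <- i + 1L
      }
    }
    out
  })
  ks <- lengths(toks)
  if (length(unique(ks)) > 1)
    stop("kmers have mixed lengths: ", paste(unique(ks), collapse = ", "))
  bad <- setdiff(unique(unlist(toks)), .KNOWN_BASES)
  if (length(bad) > 0)
    stop("unknown base symbol(s): ", paste(bad, collapse = ", "))
  matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
}

#' @rdname kmer_symbols
#' @param symbols Character matrix as produced by `kmer_symbols()`.
#' @export
symbols_to_kmer <- function(symbols, dialect = c("brackets", "nanopolish")) {
  dialect <- match.arg(dialect)
  if (is.vector(symbols)) symbols <- matrix(symbols, nrow = 1)
  toks <- matrix(format_base(symbols), nrow = nrow(symbols))
  out <- apply(toks, 1, paste, collapse = "")
  if (dialect == "nanopolish") out <- gsub("[5mC]", "M", out, fixed = TRUE)
  out
}

#' Count kmers containing a base
#'
#' Closed-form counts of kmers over an alphabet that contain a given base at
#' least once, or exactly `exactly` times: with B = |bases|,
#' at-least-one = B^k - (B-1)^k and exactly-n = choose(k, n) (B-1)^(k-n).
#'
#' @param alphabet An [alphabet()].
#' @param k Kmer length.
#' @param base Base symbol, must be in the alphabet.
#' @param exactly Optional integer occurrence count; `NULL` means "at least 1".
#' @return Integer count.
#' @examples
#' count_containing(alpha_dna(), 6, "C")                 # 3367
#' count_containing(alpha_dna("5mC"), 6, "5mC", exactly = 1) # 6144
#' @export
count_containing <- function(alphabet, k, base, exactly = NULL) {
  stopifnot(inherits(alphabet, "alphabet"))
  if (!base %in% alphabet$bases)
    stop("base '", base, "' is not in alphabet ", alphabet$name)
  B <- length(alphabet$bases)
  if (is.null(exactly)) {
    as.integer(B^k - (B - 1)^k)
  } else {
    exactly <- as.integer(exactly)
    if (exactly < 0 || exactly > k) return(0L)
    as.integer(choose(k, exactly) * (B - 1)^(k - exactly))
  }
}

# positions (columns) at which each kmer carries `base`
kmer_has_base <- function(kmers, base) {
  sym <- kmer_symbols(kmers)
  rowSums(sym == base) > 0
}
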