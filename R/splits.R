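#' Train/test partition designs
#'
#' A `split_spec` records a train/test partition of a kmer universe for one
#' experiment design, together with the parameters that produced it. The
#' designs mirror the generalization experiments used with this framework:
#' random downsampling, base dropout, position dropout, combination of two
#' base dropouts, and modification imputation.
#'
#' @param design Design label.
#' @param train,test Character vectors of kmer strings (disjoint).
#' @param params Named list of design parameters.
#' @return An object of class `split_spec`.
#' @keywords internal
split_spec <- function(design, train, test, params = list()) {
  if (length(intersect(train, test)) > 0)
    stop("train and test kmer sets overlap")
  structure(list(design = design, train = train, test = test, params = params),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  n <- length(x$train) + length(x$test)
  cat(sprintf("<split_spec:%s> train %d/%d (%.0f%%), test %d/%d (%.0f%%)\n",
              x$design, length(x$train), n, 100 * length(x$train) / n,
              length(x$test), n, 100 * length(x$test) / n))
  invisible(x)
}

#' Random downsample split
#'
#' Randomly partitions a kmer set into train/test with
#' `|train| = floor(train_fraction * |kmers|)`. Reproducible for a fixed seed.
#'
#' @param kmers Character vector of kmers (the universe).
#' @param train_fraction Fraction in (0, 1).
#' @param seed Integer seed.
#' @return A `split_spec`.
#' @examples
#' s <- random_split(enumerate_kmers(alpha_dna(), 6), 0.25, seed = 1)
#' length(s$train) # 1024
#' @export
random_split <- function(kmers, train_fraction, seed) {
  if (length(kmers) == 0) stop("empty kmer set")
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * length(kmers))
  idx <- local_seed(seed, sample.int(length(kmers), n_train))
  split_spec("downsample", kmers[sort(idx)], kmers[-sort(idx)],
             list(fraction = train_fraction, seed = seed))
}

#' Base-dropout split
#'
#' Training kmers are those containing no occurrence of `base`; every kmer
#' containing the base (at any position) goes to the test set. For an
#' alphabet of B bases this yields (B-1)^k training kmers.
#'
#' @param alphabet An [alphabet()].
#' @param k Kmer length.
#' @param base Dropped base, must be in the alphabet.
#' @return A `split_spec`.
#' @examples
#' s <- base_dropout_split(alpha_dna(), 6, "A")
#' c(length(s$train), length(s$test)) # 729 3367
#' @export
base_dropout_split <- function(alphabet, k, base) {
  if (!base %in% alphabet$bases)
    stop("base '", base, "' is not in alphabet ", alphabet$name)
  kmers <- enumerate_kmers(alphabet, k)
  has <- kmer_has_base(kmers, base)
  split_spec("base_dropout", kmers[!has], kmers[has],
             list(base = base, k = k))
}

#' Position-dropout split
#'
#' Test kmers are all kmers whose symbol at `position` equals `base`; the
#' training set is the complement. Yields B^(k-1) test kmers.
#'
#' @inheritParams base_dropout_split
#' @param position Position in 1..k.
#' @return A `split_spec`.
#' @examples
#' s <- position_dropout_split(alpha_dna(), 6, "A", 3)
#' c(length(s$train), length(s$test)) # 3072 1024
#' @export
position_dropout_split <- function(alphabet, k, base, position) {
  if (!base %in% alphabet$bases)
    stop("base '", base, "' is not in alphabet ", alphabet$name)
  position <- as.integer(position)
  if (is.na(position) || position < 1 || position > k)
    stop("position must be in 1..", k)
  kmers <- enumerate_kmers(alphabet, k)
  at <- kmer_symbols(kmers)[, position] == base
  split_spec("position_dropout", kmers[!at], kmers[at],
             list(base = base, position = position, k = k))
}

#' Combination (two-base-dropout union) split
#'
#' The training set is the union of the `base1`-dropout and `base2`-dropout
#' training sets, i.e. all kmers missing at least one of the two bases; test
#' kmers contain both bases. By inclusion-exclusion,
#' `|train| = 2 (B-1)^k - (B-2)^k`.
#'
#' @inheritParams base_dropout_split
#' @param base1,base2 Two distinct bases in the alphabet.
#' @return A `split_spec`.
#' @examples
#' s <- combination_split(alpha_dna(), 6, "G", "C")
#' c(length(s$train), length(s$test)) # 1394 2702
#' @export
combination_split <- function(alphabet, k, base1, base2) {
  if (identical(base1, base2)) stop("base1 and base2 must differ")
  for (b in c(base1, base2))
    if (!b %in% alphabet$bases)
      stop("base '", b, "' is not in alphabet ", alphabet$name)
  kmers <- enumerate_kmers(alphabet, k)
  sym <- kmer_symbols(kmers)
  has1 <- rowSums(sym == base1) > 0
  has2 <- rowSums(sym == base2) > 0
  split_spec("combination", kmers[!(has1 & has2)], kmers[has1 & has2],
             list(base1 = base1, base2 = base2, k = k))
}

#' Modification-imputation split
#'
#' Trains on every canonical kmer plus a random fraction of the
#' modification-containing kmers; the remaining modified kmers form the test
#' set. `fraction = 0` is the de novo design (no modified kmer seen in
#' training); `fraction = 1` leaves the test set empty.
#'
#' @param canonical Character vector of canonical kmers.
#' @param modified Character vector of modification-containing kmers,
#'   disjoint from `canonical`.
#' @param fraction Fraction of `modified` sampled into training, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `split_spec`; the imputation universe is
#'   `canonical` together with `modified`.
#' @export
imputation_split <- function(canonical, modified, fraction, seed) {
  if (length(intersect(canonical, modified)) > 0)
    stop("canonical and modified kmer sets overlap")
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]")
  n_imp <- floor(fraction * length(modified))
  idx <- if (n_imp > 0) sort(local_seed(seed, sample.int(length(modified), n_imp)))
         else integer(0)
  split_spec("imputation",
             c(canonical, modified[idx]),
             if (length(idx) > 0) modified[-idx] else modified,
             list(fraction = fraction, seed = seed,
                  n_canonical = length(canonical), n_imputed = n_imp))
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
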