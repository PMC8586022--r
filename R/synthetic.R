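#' Synthetic kmer-model specification
#'
#' Defines a generative model for kmer characteristic currents with known
#' ground truth: `mean(kmer) = intercept + sum over positions of
#' effect(position, base) + Gaussian(0, noise_sd)`. The additive-by-position
#' structure is the simplest signal a sequence-to-current regressor must
#' capture and admits an exact ordinary-least-squares oracle, which makes it
#' the reference for parameter-recovery tests. Default scales give pA ranges
#' comparable to real kmer models (roughly 70-130 pA).
#'
#' @param alphabet An [alphabet()].
#' @param k Kmer length.
#' @param intercept Baseline current (pA).
#' @param effect_sd Spread of the randomly drawn per-(position, base)
#'   effects (pA); ignored when `effects` is supplied.
#' @param effects Optional k x |bases| matrix of additive effects (pA), rows
#'   = positions, columns = bases in alphabet order.
#' @param noise_sd Gaussian noise added per kmer (pA, >= 0).
#' @param seed Integer seed (drives both effect drawing and noise).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(alphabet, k, intercept = 100, effect_sd = 4,
                           effects = NULL, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(alphabet, "alphabet"), k >= 1, noise_sd >= 0)
  B <- length(alphabet$bases)
  if (is.null(effects)) {
    effects <- local_seed(seed,
      matrix(stats::rnorm(k * B, 0, effect_sd), k, B))
  }
  if (!all(dim(effects) == c(k, B))) stop("effects must be k x |bases|")
  if (!all(is.finite(effects))) stop("effects must be finite")
  dimnames(effects) <- list(paste0("pos", seq_len(k)), alphabet$bases)
  structure(list(alphabet = alphabet, k = as.integer(k),
                 intercept = intercept, effects = effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic kmer model with known ground truth
#'
#' Enumerates every kmer of the spec's alphabet and assigns
#' `intercept + sum of position effects + Gaussian(0, noise_sd)` (noise
#' seeded by `spec$seed`, bit-reproducible).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `model` (a [kmer_model()]) and `effects` (the
#'   ground-truth effect table, long format: position, base, effect).
#' @export
generate_synthetic_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  kmers <- enumerate_kmers(spec$alphabet, spec$k)
  mu <- synthetic_means(spec, kmers)
  noise <- if (spec$noise_sd > 0)
    local_seed(spec$seed + 1L, stats::rnorm(length(kmers), 0, spec$noise_sd))
  else 0
  model <- kmer_model(
    data.frame(kmer = kmers, level_mean = mu + noise,
               stringsAsFactors = FALSE),
    spec$alphabet$nucleic_type, provenance = "synthetic")
  truth <- data.frame(
    position = rep(seq_len(spec$k), times = length(spec$alphabet$bases)),
    base = rep(spec$alphabet$bases, each = spec$k),
    effect = as.vector(spec$effects))
  list(model = model, effects = truth)
}

# noise-free generative means for arbitrary kmers of the spec's alphabet
synthetic_means <- function(spec, kmers) {
  sym <- kmer_symbols(kmers)
  eff <- spec$effects
  mu <- rep(spec$intercept, length(kmers))
  for (pos in seq_len(spec$k)) {
    mu <- mu + eff[pos, match(sym[, pos], colnames(eff))]
  }
  unname(mu)
}

#' Extend a synthetic reference with a modified base
#'
#' Adds a modified base to the spec's alphabet: modified kmers inherit the
#' parent base's positional effects plus a position-dependent offset applied
#' at each position where the modified base occurs; canonical entries are
#' unchanged. This emulates the role of a measured modification-containing
#' model (e.g. the nanopolish 5mC model) in imputation and de novo designs.
#'
#' @param base_spec A [synthetic_spec()] over the canonical alphabet.
#' @param mod_base Modified base symbol (e.g. `"5mC"`); its canonical parent
#'   must be in the base alphabet.
#' @param offsets Numeric vector of length k (or scalar): pA offset added to
#'   the parent effect at each position carrying the modified base.
#' @return A list with `spec` (extended [synthetic_spec()]) and `model` (the
#'   full [kmer_model()] over the extended alphabet, noise as in
#'   `base_spec`).
#' @export
make_modified_reference <- function(base_spec, mod_base, offsets) {
  stopifnot(inherits(base_spec, "synthetic_spec"))
  parent <- .MOD_PARENT[mod_base]
  if (is.na(parent)) stop("unknown modified base: ", mod_base)
  if (!parent %in% base_spec$alphabet$bases)
    stop("parent base '", parent, "' not in the base alphabet")
  offsets <- rep_len(offsets, base_spec$k)
  ext_alpha <- alphabet(c(base_spec$alphabet$bases, mod_base),
                        base_spec$alphabet$nucleic_type)
  eff <- cbind(base_spec$effects,
               base_spec$effects[, parent] + offsets)
  colnames(eff) <- ext_alpha$bases
  spec <- synthetic_spec(ext_alpha, base_spec$k,
                         intercept = base_spec$intercept,
                         effects = eff, noise_sd = base_spec$noise_sd,
                         seed = base_spec$seed)
  list(spec = spec, model = generate_synthetic_model(spec)$model)
}

#' Ordinary-least-squares oracle for additive synthetic models
#'
#' Fits per-(position, base) one-hot indicators by OLS. On a noise-free
#' synthetic model this recovers the generating effects exactly (up to the
#' usual one-redundant-level identifiability per position); with noise it is
#' the best achievable additive fit and serves as the independent reference
#' for parameter-recovery experiments with the network.
#'
#' @param model A [kmer_model()].
#' @param alphabet The [alphabet()] the kmers are drawn from.
#' @param train_kmers,test_kmers Kmer subsets for fitting and evaluation.
#' @return A list with `fit` (the `lm` object), `train_rmse`, `test_rmse`,
#'   `predict` (function: kmers -> fitted pA values).
#' @export
ols_oracle <- function(model, alphabet, train_kmers, test_kmers = NULL) {
  design <- function(kmers) {
    sym <- kmer_symbols(kmers)
    cols <- list()
    for (pos in seq_len(ncol(sym)))
      for (b in alphabet$bases[-1])  # drop one level per position
        cols[[paste0("p", pos, "_", b)]] <- as.numeric(sym[, pos] == b)
    do.call(cbind, cols)
  }
  ytr <- model_levels(model, train_kmers)
  Xtr <- design(train_kmers)
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  coefs <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred_fun <- function(kmers) drop(cbind(1, design(kmers)) %*% coefs)
  train_rmse <- sqrt(mean(fit$residuals^2))
  test_rmse <- if (!is.null(test_kmers))
    sqrt(mean((pred_fun(test_kmers) - model_levels(model, test_kmers))^2))
  else NA_real_
  list(fit = fit, train_rmse = train_rmse, test_rmse = test_rmse,
       predict = pred_fun)
}
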