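#' Goodness of fit between two kmer models
#'
#' Root mean square error (pA) and Pearson's correlation of the paired
#' level means over a kmer subset. RMSE is symmetric under argument swap; r
#' is invariant under affine rescaling (positive slope) of either argument.
#'
#' @param predicted,reference [kmer_model()] objects; `subset` must be
#'   covered by both.
#' @param subset Character vector of kmers to evaluate (default: all kmers
#'   of `reference` present in `predicted`).
#' @return A list with `rmse`, `pearson_r`, `n`. When either side has zero
#'   variance, `pearson_r` is `NA` and `zero_variance` is `TRUE`.
#' @examples
#' m <- kmer_model(data.frame(kmer = c("AA", "AC"), level_mean = c(90, 100)))
#' evaluate_fit(m, m)
#' @export
evaluate_fit <- function(predicted, reference, subset = NULL) {
  if (is.null(subset)) subset <- intersect(reference$kmer, predicted$kmer)
  p <- model_levels(predicted, subset)
  r <- model_levels(reference, subset)
  rmse <- sqrt(mean((p - r)^2))
  zero_var <- length(subset) < 2 ||
    stats::sd(p) == 0 || stats::sd(r) == 0
  pearson <- if (zero_var) NA_real_ else stats::cor(p, r)
  list(rmse = rmse, pearson_r = pearson, n = length(subset),
       zero_variance = zero_var)
}

#' Downsample fraction ladder
#'
#' The random train-test splits are taken in 5% intervals, giving 19
#' training fractions from 0.05 to 0.95.
#'
#' @return Numeric vector of training fractions.
#' @export
downsample_fractions <- function() seq(0.05, 0.95, by = 0.05)

#' Imputation fraction set
#'
#' The fractions of modification-containing kmers added to canonical
#' training in the imputation design.
#'
#' @return Numeric vector of fractions.
#' @export
imputation_fractions <- function() c(0.01, 0.05, 0.10, 0.30, 0.50, 0.70, 0.90)

# build the split for one design instance; `rep_seed` only matters for
# designs with a random split component
design_split <- function(design, alphabet, k, reference, params, rep_seed) {
  switch(design,
    downsample = random_split(enumerate_kmers(alphabet, k),
                              params$fraction, seed = rep_seed),
    base = base_dropout_split(alphabet, k, params$base),
    position = position_dropout_split(alphabet, k, params$base,
                                      params$position),
    combine = combination_split(alphabet, k, params$base1, params$base2),
    imputation = {
      canon <- enumerate_kmers(params$canonical_alphabet, k)
      modif <- setdiff(enumerate_kmers(alphabet, k), canon)
      imputation_split(canon, modif, params$fraction, seed = params$seed)
    },
    stop("unknown design: ", design))
}

#' Run one experiment design with repeats
#'
#' Trains `n_repeats` independent networks for a train/test partition design
#' and records train/test goodness of fit per repeat. For the downsample
#' design each repeat draws a fresh random split (50-fold-CV style); for
#' base/position/combination/imputation designs the split is fixed and only
#' the training stochasticity varies. Repeat seeds derive deterministically
#' from `base_seed + repeat index`.
#'
#' @param design One of `"downsample"`, `"base"`, `"position"`, `"combine"`,
#'   `"imputation"`.
#' @param reference A [kmer_model()] covering the design's kmer universe.
#' @param alphabet The [alphabet()] of the universe (for `"imputation"`, the
#'   modification-extended alphabet; supply the canonical alphabet in
#'   `params$canonical_alphabet`).
#' @param k Kmer length.
#' @param params Named list of design parameters (`fraction`, `base`,
#'   `position`, `base1`/`base2`, `seed` as appropriate).
#' @param config A [gcn_config()].
#' @param tc A [train_config()] template; per-repeat seeds override
#'   `tc$seed`.
#' @param n_repeats Number of independently trained networks.
#' @param base_seed Base of the per-repeat seed sequence.
#' @return A long-format data.frame: one row per (repeat, subset) with
#'   columns `design`, `param`, `repeat_index`, `seed`, `subset`, `rmse`,
#'   `pearson_r`, `n`.
#' @export
run_experiment <- function(design, reference, alphabet, k, params = list(),
                           config = reduced_config(alphabet$nucleic_type),
                           tc = train_config(), n_repeats = 1L,
                           base_seed = 1L) {
  universe <- enumerate_kmers(alphabet, k)
  missing_k <- setdiff(universe, reference$kmer)
  if (length(missing_k) > 0)
    stop("reference model lacks ", length(missing_k), " kmer(s), e.g. ",
         paste(utils::head(missing_k, 3), collapse = ", "))
  P <- padding_size(alphabet, k)
  tensors <- encode_kmers(universe, alphabet$nucleic_type, P)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    seed_i <- as.integer(base_seed + rep_i)
    sp <- design_split(design, alphabet, k, reference, params, seed_i)
    tci <- tc
    tci$seed <- seed_i
    mdl <- build_gcn_model(config, P)
    tr_tensors <- subset_tensors(tensors, match(sp$train, universe))
    mdl <- train_gcn(mdl, tr_tensors, model_levels(reference, sp$train), tci)
    pred <- predict(mdl, tensors)
    for (subset_name in c("train", "test")) {
      km <- sp[[subset_name]]
      if (length(km) == 0) next
      m <- evaluate_fit(pred, reference, km)
      rows[[length(rows) + 1L]] <- data.frame(
        design = design,
        param = paste(names(params), unlist(lapply(params, format)),
                      sep = "=", collapse = ","),
        repeat_index = rep_i, seed = seed_i, subset = subset_name,
        rmse = m$rmse, pearson_r = m$pearson_r, n = m$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' De novo prediction of modified kmers
#'
#' Trains networks on a canonical reference only and predicts the full kmer
#' model over a modification-extended alphabet (e.g. canonical {A,T,C,G}
#' training applied to all 15,625 {A,T,C,G,5mC} 6mers). The network never
#' sees the modified base; it must generalize its chemistry (such as the
#' 5-methyl group shared between thymine and 5mC) from the canonical kmers.
#'
#' @param reference_canonical A [kmer_model()] over the canonical alphabet.
#' @param canonical_alphabet,target_alphabet [alphabet()]s; the target
#'   extends the canonical one.
#' @param k Kmer length.
#' @param config A [gcn_config()].
#' @param tc A [train_config()] template.
#' @param n_repeats Number of independently trained networks.
#' @param base_seed Base of the per-repeat seed sequence.
#' @return A list with `summary` (a [kmer_model()]: per-kmer mean over
#'   repeats) and `repeats` (list of per-repeat [kmer_model()]s).
#' @export
denovo_prediction <- function(reference_canonical, canonical_alphabet,
                              target_alphabet, k,
                              config = reduced_config(target_alphabet$nucleic_type),
                              tc = train_config(), n_repeats = 1L,
                              base_seed = 1L) {
  if (!all(canonical_alphabet$bases %in% target_alphabet$bases))
    stop("target alphabet must extend the canonical alphabet")
  train_kmers <- enumerate_kmers(canonical_alphabet, k)
  target_kmers <- enumerate_kmers(target_alphabet, k)
  P <- padding_size(list(canonical_alphabet, target_alphabet), k)
  nt <- target_alphabet$nucleic_type
  train_tensors <- encode_kmers(train_kmers, nt, P)
  target_tensors <- encode_kmers(target_kmers, nt, P)
  y <- model_levels(reference_canonical, train_kmers)
  preds <- matrix(NA_real_, length(target_kmers), n_repeats)
  repeats <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    tci <- tc
    tci$seed <- base_seed + rep_i
    mdl <- build_gcn_model(config, P)
    mdl <- train_gcn(mdl, train_tensors, y, tci)
    pm <- predict(mdl, target_tensors)
    repeats[[rep_i]] <- pm
    preds[, rep_i] <- pm$level_mean
  }
  summary <- kmer_model(
    data.frame(kmer = target_kmers, level_mean = rowMeans(preds),
               stringsAsFactors = FALSE),
    nt, provenance = "denovo_mean_over_repeats")
  list(summary = summary, repeats = repeats)
}
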