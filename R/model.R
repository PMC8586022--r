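#' Architecture configuration
#'
#' Describes the regression network: a stack of graph-convolution layers
#' (widths follow the [node_counts()] ladder), a stack of 1-D convolutional
#' layers with ReLU and 2 x 2 average pooling (stride 1), a row-wise flatten,
#' a dense layer, and a scalar linear output.
#'
#' @param n_gcn_layers Number of GCN layers.
#' @param n_cnn_layers Number of 1-D CNN layers.
#' @param kernel_size Convolution kernel size K (>= 1).
#' @param dense_nodes Width N of the dense layer.
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param pool_size Average-pooling patch size (2).
#' @return An object of class `gcn_config`.
#' @examples
#' gcn_config(4, 3, 10, 8192, "DNA")  # the tuned DNA architecture
#' reduced_config("DNA")              # desk-scale configuration
#' @export
gcn_config <- function(n_gcn_layers, n_cnn_layers, kernel_size, dense_nodes,
                       nucleic_type = c("DNA", "RNA"), pool_size = 2L) {
  nucleic_type <- match.arg(nucleic_type)
  stopifnot(n_gcn_layers >= 1, n_cnn_layers >= 1, kernel_size >= 1,
            dense_nodes >= 1, pool_size == 2L)
  structure(list(n_gcn_layers = as.integer(n_gcn_layers),
                 n_cnn_layers = as.integer(n_cnn_layers),
                 kernel_size = as.integer(kernel_size),
                 dense_nodes = as.integer(dense_nodes),
                 nucleic_type = nucleic_type,
                 pool_size = as.integer(pool_size)),
            class = "gcn_config")
}

#' @rdname gcn_config
#' @export
reduced_config <- function(nucleic_type = c("DNA", "RNA")) {
  gcn_config(2, 2, 4, 128, match.arg(nucleic_type))
}

#' Tuned architectures
#'
#' The grid-search optima: DNA `(4 GCN, 3 CNN, K = 10, 8192)`, canonical RNA
#' `(4, 5, 10, 8192)`, modified RNA `(6, 6, 10, 8192)`.
#'
#' @param which `"dna"`, `"rna"`, or `"rna_modified"`.
#' @return A [gcn_config()].
#' @export
tuned_config <- function(which = c("dna", "rna", "rna_modified")) {
  switch(match.arg(which),
         dna = gcn_config(4, 3, 10, 8192, "DNA"),
         rna = gcn_config(4, 5, 10, 8192, "RNA"),
         rna_modified = gcn_config(6, 6, 10, 8192, "RNA"))
}

#' Training configuration
#'
#' Defaults follow the training procedure used throughout: Adam with its
#' canonical hyperparameters, mean-squared-error loss, at most 500 epochs,
#' early stopping on the validation loss with patience 10, and 10% dropout
#' after every layer during training.
#'
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param dropout_rate Dropout rate applied after each layer at train time.
#' @param validation_fraction Fraction of the training kmers held out to
#'   monitor the validation loss.
#' @param batch_size Minibatch size.
#' @param learning_rate,beta1,beta2,epsilon Adam optimizer settings.
#' @param seed Integer seed controlling weight initialization, the
#'   validation split, shuffling, and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(max_epochs = 500L, patience = 10L,
                         dropout_rate = 0.10, validation_fraction = 0.10,
                         batch_size = 32L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = 1L) {
  stopifnot(max_epochs >= 1, patience >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            validation_fraction > 0, validation_fraction < 1,
            batch_size >= 1, learning_rate > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 dropout_rate = dropout_rate,
                 validation_fraction = validation_fraction,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

# layer-by-layer shape plan; errors carry the index of the collapsing layer
plan_shapes <- function(config, P, n_features = 8L) {
  gw <- node_counts(config$n_gcn_layers)
  cw <- node_counts(config$n_cnn_layers)
  K <- config$kernel_size
  L <- as.integer(P); cc <- gw[length(gw)]
  conv_dims <- list()
  for (l in seq_len(config$n_cnn_layers)) {
    Lc <- L - K + 1L
    if (Lc < 1L)
      stop("configuration error: CNN layer ", l,
           " output length collapses (", L, " - ", K, " + 1 < 1)")
    conv_dims[[l]] <- list(L_in = L, c_in = cc, L_conv = Lc, c_conv = cw[l])
    L <- Lc - 1L           # 2 x 2 average pooling, stride 1
    cc <- cw[l] - 1L
    if (L < 1L || cc < 1L)
      stop("configuration error: pooling after CNN layer ", l,
           " collapses output to {", L, ", ", cc, "}")
  }
  list(gcn_widths = gw, cnn_widths = cw, conv_dims = conv_dims,
       flat_len = L * cc, final_L = L, final_c = cc,
       n_features = as.integer(n_features))
}

#' Build the regression network
#'
#' Validates the layer-by-layer shape contract for the given padding size
#' and initializes all weights (Glorot-uniform, seeded). The model maps a
#' padded molecular graph `(A, X)` to a single ionic-current value in pA.
#'
#' @param config A [gcn_config()].
#' @param P Padding size (number of tensor rows), e.g. from
#'   [padding_size()].
#' @param n_features Number of atom features (8).
#' @param seed Optional seed for weight initialization.
#' @return An object of class `gcn_model` holding the configuration, shape
#'   plan, and parameter tensors.
#' @export
build_gcn_model <- function(config, P, n_features = 8L, seed = NULL) {
  stopifnot(inherits(config, "gcn_config"))
  shapes <- plan_shapes(config, P, n_features)
  init <- function() {
    gw <- shapes$gcn_widths
    K <- config$kernel_size
    Wg <- list()
    fin <- shapes$n_features
    for (l in seq_along(gw)) {
      Wg[[l]] <- glorot(fin, gw[l])
      fin <- gw[l]
    }
    conv <- list()
    for (l in seq_along(shapes$conv_dims)) {
      d <- shapes$conv_dims[[l]]
      conv[[l]] <- list(W = glorot(K * d$c_in, d$c_conv),
                        b = numeric(d$c_conv))
    }
    list(Wg = Wg, conv = conv,
         Wd = glorot(shapes$flat_len, config$dense_nodes),
         bd = numeric(config$dense_nodes),
         Wo = glorot(config$dense_nodes, 1L),
         bo = 0)
  }
  params <- if (is.null(seed)) init() else local_seed(seed, init())
  structure(list(config = config, P = as.integer(P), shapes = shapes,
                 params = params, y_center = 0, y_scale = 1,
                 history = NULL, train_fingerprint = NULL),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  s <- x$shapes
  cat(sprintf(
    "<gcn_model> P=%d | GCN %s | CNN %s (K=%d) | flatten %d | dense %d | 1\n",
    x$P, paste(s$gcn_widths, collapse = "-"),
    paste(s$cnn_widths, collapse = "-"), x$config$kernel_size,
    s$flat_len, x$config$dense_nodes))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs (best val MSE %.4g pA^2)\n",
                nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

# full forward pass over a batch given stacked inputs; returns prediction
# (standardized scale) and, when `training`, all caches for backprop
forward_pass <- function(model, Ab, Xb, n, training = FALSE, rate = 0) {
  P <- model$P
  s <- model$shapes
  caches <- list(gcn = list(), conv = list())
  H <- Xb
  for (l in seq_along(model$params$Wg)) {
    AH <- as.matrix(Ab %*% H)
    Z <- AH %*% model$params$Wg[[l]]
    Hact <- elu(Z)
    dp <- dropout_forward(Hact, rate, training)
    caches$gcn[[l]] <- list(AH = AH, Z = Z, mask = dp$mask)
    H <- dp$out
  }
  for (l in seq_along(model$params$conv)) {
    d <- s$conv_dims[[l]]
    cv <- conv1d_forward(H, model$params$conv[[l]]$W,
                         model$params$conv[[l]]$b, n, d$L_in,
                         model$config$kernel_size)
    Hr <- relu(cv$Z)
    dp <- dropout_forward(Hr, rate, training)
    pl <- avgpool_forward(dp$out, n, cv$L_out)
    caches$conv[[l]] <- list(Z = cv$Z, Xcol = cv$Xcol, r0 = cv$r0,
                             mask = dp$mask, rp = pl$rp, L_out = cv$L_out,
                             c_conv = d$c_conv, d = d)
    H <- pl$Y
  }
  Fl <- flatten_forward(H, n)
  D <- sweep(Fl %*% model$params$Wd, 2, model$params$bd, "+")
  dpD <- dropout_forward(D, rate, training)
  pred <- drop(dpD$out %*% model$params$Wo) + model$params$bo
  caches$Fl <- Fl
  caches$Dd <- dpD$out
  caches$maskD <- dpD$mask
  list(pred = pred, caches = caches)
}

backward_pass <- function(model, fw, dPred, n) {
  s <- model$shapes
  K <- model$config$kernel_size
  rate_scale <- function(dX, mask) if (is.null(mask)) dX else dX * mask
  g <- list(conv = list())
  dPred <- matrix(dPred, ncol = 1)
  g$Wo <- crossprod(fw$caches$Dd, dPred)
  g$bo <- sum(dPred)
  dD <- rate_scale(dPred %*% t(model$params$Wo), fw$caches$maskD)
  g$Wd <- crossprod(fw$caches$Fl, dD)
  g$bd <- colSums(dD)
  dH <- flatten_backward(dD %*% t(model$params$Wd), s$final_L, s$final_c)
  for (l in rev(seq_along(model$params$conv))) {
    cc <- fw$caches$conv[[l]]
    dPool <- avgpool_backward(dH, cc$rp, n, cc$L_out, cc$c_conv)
    dZ <- rate_scale(dPool, cc$mask) * (cc$Z > 0)
    bk <- conv1d_backward(dZ, cc$Xcol, model$params$conv[[l]]$W, cc$r0,
                          n, cc$d$L_in, K, cc$d$c_in)
    g$conv[[l]] <- list(W = bk$dW, b = bk$db)
    dH <- bk$dX
  }
  g$Wg <- vector("list", length(model$params$Wg))
  for (l in rev(seq_along(model$params$Wg))) {
    cg <- fw$caches$gcn[[l]]
    dZ <- rate_scale(dH, cg$mask) * elu_grad(cg$Z)
    g$Wg[[l]] <- crossprod(cg$AH, dZ)
    dHin <- dZ %*% t(model$params$Wg[[l]])
    if (l > 1) dH <- as.matrix(fw$Ab %*% dHin)  # Ahat is symmetric
  }
  g
}

# flatten parameter/gradient trees into aligned lists for the optimizer
param_leaves <- function(p) {
  out <- list(p$Wo, p$bo, p$Wd, p$bd)
  for (l in seq_along(p$Wg)) out[[length(out) + 1L]] <- p$Wg[[l]]
  for (l in seq_along(p$conv)) {
    out[[length(out) + 1L]] <- p$conv[[l]]$W
    out[[length(out) + 1L]] <- p$conv[[l]]$b
  }
  out
}

set_param_leaves <- function(p, leaves) {
  p$Wo <- leaves[[1]]; p$bo <- leaves[[2]]
  p$Wd <- leaves[[3]]; p$bd <- leaves[[4]]
  i <- 5L
  for (l in seq_along(p$Wg)) { p$Wg[[l]] <- leaves[[i]]; i <- i + 1L }
  for (l in seq_along(p$conv)) {
    p$conv[[l]]$W <- leaves[[i]]; i <- i + 1L
    p$conv[[l]]$b <- leaves[[i]]; i <- i + 1L
  }
  p
}

#' Train the network on encoded kmers
#'
#' Minibatch Adam on the mean-squared error, with an internal held-out
#' validation split for early stopping (stop after `patience` epochs without
#' validation improvement; the best-validation weights are restored).
#' Targets are standardized internally and predictions are returned in pA.
#' Fully reproducible for a fixed `tc$seed` on a single thread.
#'
#' @param model A [build_gcn_model()] object.
#' @param tensors A `kmer_tensors` object from [encode_kmers()].
#' @param targets Numeric vector of characteristic ionic currents (pA), one
#'   per encoded kmer.
#' @param tc A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `gcn_model`, with `history` (per-epoch train and
#'   validation MSE, pA^2) and a fingerprint of the training kmer set.
#' @export
train_gcn <- function(model, tensors, targets, tc = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "gcn_model"), inherits(tensors, "kmer_tensors"),
            inherits(tc, "train_config"))
  nall <- length(tensors$Ahat)
  if (length(targets) != nall) stop("one target per encoded kmer required")
  if (nall < 2) stop("need at least 2 training kmers")
  local_seed(tc$seed, {
    model$params <- local({  # re-draw weights under the training seed
      m <- build_gcn_model(model$config, model$P, model$shapes$n_features)
      m$params
    })
    n_val <- max(1L, floor(tc$validation_fraction * nall))
    if (n_val >= nall) n_val <- nall - 1L
    val_idx <- sample.int(nall, n_val)
    tr_idx <- setdiff(seq_len(nall), val_idx)
    y_center <- mean(targets[tr_idx])
    y_scale <- stats::sd(targets[tr_idx])
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
    y <- (targets - y_center) / y_scale
    model$y_center <- y_center
    model$y_scale <- y_scale

    Ab_val <- Matrix::bdiag(tensors$Ahat[val_idx])
    Xb_val <- do.call(rbind, tensors$X[val_idx])
    leaves <- param_leaves(model$params)
    mom <- lapply(leaves, function(x) x * 0)
    vel <- lapply(leaves, function(x) x * 0)
    t_step <- 0L
    best <- list(loss = Inf, leaves = leaves, epoch = 0L)
    hist_tr <- numeric(0); hist_val <- numeric(0)
    for (epoch in seq_len(tc$max_epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
      ep_loss <- 0
      for (bidx in batches) {
        nb <- length(bidx)
        Ab <- Matrix::bdiag(tensors$Ahat[bidx])
        Xb <- do.call(rbind, tensors$X[bidx])
        fw <- forward_pass(model, Ab, Xb, nb, training = TRUE,
                           rate = tc$dropout_rate)
        fw$Ab <- Ab
        res <- fw$pred - y[bidx]
        loss <- mean(res^2)
        if (!is.finite(loss)) stop("training diverged (non-finite loss)")
        ep_loss <- ep_loss + loss * nb
        grads <- backward_pass(model, fw, 2 * res / nb, nb)
        gl <- param_leaves(grads)
        t_step <- t_step + 1L
        for (i in seq_along(leaves)) {
          mom[[i]] <- tc$beta1 * mom[[i]] + (1 - tc$beta1) * gl[[i]]
          vel[[i]] <- tc$beta2 * vel[[i]] + (1 - tc$beta2) * gl[[i]]^2
          mhat <- mom[[i]] / (1 - tc$beta1^t_step)
          vhat <- vel[[i]] / (1 - tc$beta2^t_step)
          leaves[[i]] <- leaves[[i]] -
            tc$learning_rate * mhat / (sqrt(vhat) + tc$epsilon)
        }
        model$params <- set_param_leaves(model$params, leaves)
      }
      fw_val <- forward_pass(model, Ab_val, Xb_val, n_val)
      val_loss <- mean((fw_val$pred - y[val_idx])^2)
      if (!is.finite(val_loss)) stop("training diverged (non-finite loss)")
      hist_tr <- c(hist_tr, ep_loss / length(tr_idx))
      hist_val <- c(hist_val, val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        ep_loss / length(tr_idx), val_loss))
      if (val_loss < best$loss)
        best <- list(loss = val_loss, leaves = leaves, epoch = epoch)
      if (epoch - best$epoch >= tc$patience) break
    }
    model$params <- set_param_leaves(model$params, best$leaves)
    model$history <- data.frame(epoch = seq_along(hist_tr),
                                train_loss = hist_tr * y_scale^2,
                                val_loss = hist_val * y_scale^2)
    model$train_fingerprint <- digest_kmers(tensors$kmers)
    model$trained <- TRUE
    model
  })
}

digest_kmers <- function(kmers) {
  v <- sort(kmers)
  sprintf("%d:%s:%s", length(v), v[1], v[length(v)])
}

#' Predict kmer characteristic ionic currents
#'
#' Applies a trained model (dropout disabled) to kmers or pre-encoded
#' tensors; deterministic for a fixed trained model.
#'
#' @param object A trained `gcn_model`.
#' @param kmers Character vector of kmers, or a `kmer_tensors` object.
#' @param batch_size Prediction batch size.
#' @param ... Unused.
#' @return A `kmer_model` data.frame with columns `kmer`, `level_mean` (pA).
#' @export
predict.gcn_model <- function(object, kmers, batch_size = 256L, ...) {
  tensors <- if (inherits(kmers, "kmer_tensors")) kmers
    else encode_kmers(kmers, object$config$nucleic_type, object$P)
  nall <- length(tensors$Ahat)
  preds <- numeric(nall)
  for (start in seq(1L, nall, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nall)
    Ab <- Matrix::bdiag(tensors$Ahat[idx])
    Xb <- do.call(rbind, tensors$X[idx])
    preds[idx] <- forward_pass(object, Ab, Xb, length(idx))$pred
  }
  kmer_model(data.frame(kmer = tensors$kmers,
                        level_mean = preds * object$y_scale + object$y_center,
                        stringsAsFactors = FALSE),
             nucleic_type = object$config$nucleic_type,
             provenance = "gcn_prediction")
}

#' Hyperparameter grid and k-fold cross-validated search
#'
#' `table_grid()` enumerates the canonical 500-combination search space
#' (GCN layers x CNN layers x kernel size x dense nodes =
#' 5 x 5 x 4 x 5). `grid_search()` evaluates each combination by k-fold
#' cross-validation and returns the configuration with the lowest mean fold
#' RMSE; combinations whose shapes collapse for the given padding size are
#' skipped with a recorded reason.
#'
#' @param grid Data frame with columns `n_gcn_layers`, `n_cnn_layers`,
#'   `kernel_size`, `dense_nodes` (see `table_grid()`).
#' @param tensors A `kmer_tensors` training set.
#' @param targets Numeric targets (pA).
#' @param nucleic_type `"DNA"` or `"RNA"`.
#' @param folds Number of CV folds (default 10); the folds partition the
#'   dataset exhaustively and disjointly.
#' @param tc A [train_config()]; fold seeds derive from `tc$seed`.
#' @return A list with `best` (a [gcn_config()]), `results` (one row per
#'   combination: mean/sd fold RMSE or the skip reason).
#' @export
grid_search <- function(grid, tensors, targets, nucleic_type, folds = 10L,
                        tc = train_config()) {
  stopifnot(inherits(tensors, "kmer_tensors"))
  nall <- length(tensors$Ahat)
  if (nall < folds) stop("dataset smaller than the number of folds")
  fold_id <- local_seed(tc$seed,
                        sample(rep(seq_len(folds), length.out = nall)))
  results <- grid
  results$mean_rmse <- NA_real_
  results$sd_rmse <- NA_real_
  results$status <- "ok"
  for (i in seq_len(nrow(grid))) {
    cfg <- try(gcn_config(grid$n_gcn_layers[i], grid$n_cnn_layers[i],
                          grid$kernel_size[i], grid$dense_nodes[i],
                          nucleic_type), silent = TRUE)
    shapes <- if (inherits(cfg, "try-error")) cfg else
      try(plan_shapes(cfg, tensors$P), silent = TRUE)
    if (inherits(shapes, "try-error")) {
      results$status[i] <- conditionMessage(attr(shapes, "condition"))
      next
    }
    rmses <- numeric(folds)
    for (f in seq_len(folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      sub <- subset_tensors(tensors, tr)
      tcf <- tc
      tcf$seed <- tc$seed + f
      mdl <- build_gcn_model(cfg, tensors$P)
      mdl <- train_gcn(mdl, sub, targets[tr], tcf)
      pr <- predict(mdl, subset_tensors(tensors, te))
      rmses[f] <- sqrt(mean((pr$level_mean - targets[te])^2))
    }
    results$mean_rmse[i] <- mean(rmses)
    results$sd_rmse[i] <- stats::sd(rmses)
  }
  ok <- which(!is.na(results$mean_rmse))
  if (length(ok) == 0) stop("no valid configuration in the grid")
  bi <- ok[which.min(results$mean_rmse[ok])]
  list(best = gcn_config(results$n_gcn_layers[bi], results$n_cnn_layers[bi],
                         results$kernel_size[bi], results$dense_nodes[bi],
                         nucleic_type),
       results = results)
}

#' @rdname grid_search
#' @export
table_grid <- function() {
  expand.grid(n_gcn_layers = c(2L, 3L, 4L, 5L, 6L),
              n_cnn_layers = c(2L, 3L, 4L, 5L, 6L),
              kernel_size = c(2L, 4L, 10L, 20L),
              dense_nodes = c(32L, 128L, 512L, 2048L, 8192L))
}

subset_tensors <- function(tensors, idx) {
  structure(list(Ahat = tensors$Ahat[idx], X = tensors$X[idx],
                 n_real = tensors$n_real[idx], kmers = tensors$kmers[idx],
                 P = tensors$P),
            class = "kmer_tensors")
}
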