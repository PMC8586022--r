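test_that("adjacency normalization matches closed forms", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  two <- normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
  expect_equal(two, matrix(0.5, 2, 2))
  # path graph on 3 nodes: degrees (2, 3, 2) after self-loops
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  Ahat <- normalize_adjacency(A)
  expect_equal(diag(Ahat), c(1 / 2, 1 / 3, 1 / 2))
  expect_equal(Ahat[1, 2], 1 / sqrt(6))
  expect_equal(Ahat[1, 3], 0)
  expect_error(normalize_adjacency(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("gcn_layer agrees with the brute-force neighbour oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    A <- random_adjacency(n)
    H <- matrix(rnorm(n * 3), n, 3)
    W <- matrix(rnorm(3 * 4), 3, 4)
    expect_equal(gcn_layer(normalize_adjacency(A), H, W),
                 gcn_oracle(A, H, W), tolerance = 1e-6)
  }
  # identity operator with identity weights passes non-negatives through
  H <- matrix(abs(rnorm(12)), 4, 3)
  expect_equal(gcn_layer(diag(4), H, diag(3)), H)
  expect_error(gcn_layer(diag(3), matrix(0, 4, 2), diag(2)), "conformable")
})

test_that("layer-width ladder follows 16 * 2^(l-1)", {
  expect_identical(node_counts(4), c(128L, 64L, 32L, 16L))
  expect_identical(node_counts(1), 16L)
  expect_identical(node_counts(6), c(512L, 256L, 128L, 64L, 32L, 16L))
  expect_error(node_counts(0), "positive")
})

test_that("shape plans follow the printed convolution recurrences", {
  dna <- build_gcn_model(tuned_config("dna"), 133)
  # first CNN output length: 133 - 10 + 1
  expect_identical(dna$shapes$conv_dims[[1]]$L_conv, 124L)
  expect_identical(dna$shapes$gcn_widths, c(128L, 64L, 32L, 16L))
  # each pooled layer loses one row and one channel
  d2 <- dna$shapes$conv_dims[[2]]
  expect_identical(d2$L_in, 123L); expect_identical(d2$c_in, 63L)
  expect_identical(dna$shapes$flat_len,
                   dna$shapes$final_L * dna$shapes$final_c)
  # the tuned modified-RNA architecture also builds
  rna <- build_gcn_model(tuned_config("rna_modified"), 116)
  expect_identical(rna$shapes$gcn_widths[1], 512L)
  expect_identical(rna$shapes$conv_dims[[1]]$L_conv, 107L)
  # dimension collapse is reported with the failing layer index
  expect_error(build_gcn_model(gcn_config(2, 6, 20, 32, "DNA"), 45),
               "CNN layer 3")
})

test_that("padded atoms stay inert through the GCN stack", {
  alpha <- alpha_dna()
  tens <- encode_kmers("AT", "DNA", 60)  # 42 real atoms, 18 padded
  H <- tens$X[[1]]
  Ahat <- tens$Ahat[[1]]
  set.seed(4)
  H <- gcn_layer(Ahat, H, matrix(rnorm(8 * 5), 8, 5))
  expect_true(all(H[43:60, ] == 0))
  H <- gcn_layer(Ahat, H, matrix(rnorm(5 * 3), 5, 3))
  expect_true(all(H[43:60, ] == 0))
})

test_that("training fits constant targets and improves over epoch 1", {
  alpha <- alpha_dna()
  kmers <- enumerate_kmers(alpha, 2)
  tens <- encode_kmers(kmers, "DNA", padding_size(alpha, 2))
  mdl <- build_gcn_model(micro_config(), tens$P)
  fit <- train_gcn(mdl, tens, rep(100, 16), micro_tc(epochs = 10))
  pred <- predict(fit, tens)
  expect_lt(sqrt(mean((pred$level_mean - 100)^2)), 0.5)
  expect_lte(min(fit$history$train_loss), fit$history$train_loss[1])
  expect_lte(nrow(fit$history), 10)
})

test_that("training and prediction are reproducible for a fixed seed", {
  alpha <- alpha_dna()
  kmers <- enumerate_kmers(alpha, 2)
  tens <- encode_kmers(kmers, "DNA", padding_size(alpha, 2))
  y <- seq(90, 120, length.out = 16)
  f1 <- train_gcn(build_gcn_model(micro_config(), tens$P), tens, y,
                  micro_tc(epochs = 4, seed = 42))
  f2 <- train_gcn(build_gcn_model(micro_config(), tens$P), tens, y,
                  micro_tc(epochs = 4, seed = 42))
  expect_identical(predict(f1, tens)$level_mean, predict(f2, tens)$level_mean)
  expect_identical(f1$history, f2$history)
  f3 <- train_gcn(build_gcn_model(micro_config(), tens$P), tens, y,
                  micro_tc(epochs = 4, seed = 43))
  expect_false(identical(predict(f1, tens)$level_mean,
                         predict(f3, tens)$level_mean))
  # prediction itself is deterministic (dropout disabled)
  expect_identical(predict(f1, "AT")$level_mean, predict(f1, "AT")$level_mean)
})

test_that("grid search returns the single config of a singleton grid", {
  alpha <- alpha_dna()
  kmers <- enumerate_kmers(alpha, 2)
  tens <- encode_kmers(kmers, "DNA", padding_size(alpha, 2))
  y <- seq(90, 120, length.out = 16)
  grid <- data.frame(n_gcn_layers = 1L, n_cnn_layers = 1L,
                     kernel_size = 2L, dense_nodes = 16L)
  gs <- grid_search(grid, tens, y, "DNA", folds = 2, tc = micro_tc(2))
  expect_identical(gs$best$n_gcn_layers, 1L)
  expect_true(is.finite(gs$results$mean_rmse[1]))
  # collapsing configurations are skipped with a recorded reason
  grid2 <- rbind(grid, data.frame(n_gcn_layers = 1L, n_cnn_layers = 6L,
                                  kernel_size = 20L, dense_nodes = 16L))
  gs2 <- grid_search(grid2, tens, y, "DNA", folds = 2, tc = micro_tc(2))
  expect_match(gs2$results$status[2], "collapse")
  expect_identical(nrow(table_grid()), 500L)
})
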