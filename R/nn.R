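# Layer primitives for the graph-convolutional regression network. All dense
# algebra goes through BLAS; per-kmer graph operators are sparse and batches
# are processed as block-diagonal systems.

#' Renormalized graph convolution operator
#'
#' Given a symmetric binary adjacency matrix A with zero diagonal, adds
#' self-edges (A + I) and symmetrically normalizes by the square root of the
#' augmented degree: `D^(-1/2) (A + I) D^(-1/2)`. The normalization keeps the
#' scale of node feature vectors stable across layers; zero-padded atoms
#' receive self-degree 1 from the identity term, so padded rows stay inert.
#'
#' @param A Symmetric binary matrix (zero diagonal).
#' @return Dense numeric matrix of the same size.
#' @examples
#' normalize_adjacency(matrix(0, 1, 1))         # 1
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2)) # all entries 1/2
#' @export
normalize_adjacency <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A) || !isTRUE(all.equal(A, t(A))))
    stop("adjacency matrix must be square and symmetric")
  At <- A + diag(nrow(A))
  dis <- 1 / sqrt(rowSums(At))
  At * outer(dis, dis)
}

#' Exponential linear unit
#'
#' @param x Numeric array.
#' @param alpha Saturation scale for negative inputs.
#' @return `x` for positive entries, `alpha * (exp(x) - 1)` otherwise.
#' @export
elu <- function(x, alpha = 1) {
  ifelse(x > 0, x, alpha * (exp(x) - 1))
}

elu_grad <- function(x, alpha = 1) {
  ifelse(x > 0, 1, alpha * exp(x))
}

relu <- function(x) pmax(x, 0)

#' Single graph-convolution layer
#'
#' Computes `activation(Ahat %*% H %*% W)`: every atom's feature vector is
#' mixed with those of its covalently bonded neighbours through the
#' normalized operator `Ahat`, then linearly transformed and passed through
#' the activation (ELU by default).
#'
#' @param Ahat Normalized adjacency operator (see [normalize_adjacency()]).
#' @param H Input activations, atoms x features (`H^(0)` is the atom feature
#'   matrix X).
#' @param W Weight matrix, in-features x out-features.
#' @param activation Activation function.
#' @return Matrix of output activations, atoms x out-features.
#' @export
gcn_layer <- function(Ahat, H, W, activation = elu) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (ncol(Ahat) != nrow(H)) stop("Ahat and H are not conformable")
  if (ncol(H) != nrow(W)) stop("H and W are not conformable")
  activation(as.matrix(Ahat %*% H) %*% W)
}

#' Layer-width ladder
#'
#' Widths of a layer group of the given depth follow `n = 16 * 2^(l - 1)`
#' counted from the output side, i.e. listed input-to-output as
#' `[16 * 2^(depth-1), ..., 32, 16]`.
#'
#' @param group_depth Number of layers in the group (>= 1).
#' @return Integer vector of layer widths, input to output.
#' @examples
#' node_counts(4) # 128 64 32 16
#' @export
node_counts <- function(group_depth) {
  group_depth <- as.integer(group_depth)
  if (is.na(group_depth) || group_depth < 1)
    stop("group_depth must be a positive integer")
  as.integer(16 * 2^((group_depth:1) - 1))
}

# row index template for sample-major stacked matrices: for n samples whose
# blocks have L rows, returns the rows of positions 1..L_out in every block
block_rows <- function(n, L, L_out) {
  rep((0:(n - 1)) * L, each = L_out) + rep(seq_len(L_out), n)
}

# 1-D valid convolution via im2col on a sample-major stacked matrix
# Xb: (n*L) x c_in; W: (K*c_in) x c_out, k-major blocks; returns (n*L_out) x c_out
conv1d_forward <- function(Xb, W, b, n, L, K) {
  L_out <- L - K + 1L
  r0 <- block_rows(n, L, L_out)
  Xcol <- do.call(cbind, lapply(seq_len(K), function(k)
    Xb[r0 + (k - 1L), , drop = FALSE]))
  Z <- Xcol %*% W
  Z <- sweep(Z, 2, b, "+")
  list(Z = Z, Xcol = Xcol, r0 = r0, L_out = L_out)
}

conv1d_backward <- function(dZ, Xcol, W, r0, n, L, K, c_in) {
  dW <- crossprod(Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- dZ %*% t(W)
  dXb <- matrix(0, n * L, c_in)
  for (k in seq_len(K)) {
    cols <- ((k - 1L) * c_in + 1L):(k * c_in)
    idx <- r0 + (k - 1L)
    dXb[idx, ] <- dXb[idx, ] + dXcol[, cols, drop = FALSE]
  }
  list(dW = dW, db = db, dX = dXb)
}

# 2 x 2 average pooling, stride 1, over the (length x channels) matrix of
# each sample block; output block is (L-1) x (c-1)
avgpool_forward <- function(Xb, n, L) {
  c_in <- ncol(Xb)
  rp <- block_rows(n, L, L - 1L)
  Y <- 0.25 * (Xb[rp, 1:(c_in - 1), drop = FALSE] +
               Xb[rp + 1L, 1:(c_in - 1), drop = FALSE] +
               Xb[rp, 2:c_in, drop = FALSE] +
               Xb[rp + 1L, 2:c_in, drop = FALSE])
  list(Y = Y, rp = rp)
}

avgpool_backward <- function(dY, rp, n, L, c_in) {
  dX <- matrix(0, n * L, c_in)
  g <- 0.25 * dY
  lo <- 1:(c_in - 1); hi <- 2:c_in
  dX[rp, lo] <- dX[rp, lo] + g
  dX[rp + 1L, lo] <- dX[rp + 1L, lo] + g
  dX[rp, hi] <- dX[rp, hi] + g
  dX[rp + 1L, hi] <- dX[rp + 1L, hi] + g
  dX
}

# row-wise flatten of sample-major stacked blocks: (n*L) x c -> n x (L*c)
flatten_forward <- function(Xb, n) {
  matrix(as.vector(t(Xb)), nrow = n, byrow = TRUE)
}

flatten_backward <- function(dF, L, c_out) {
  matrix(as.vector(t(dF)), ncol = c_out, byrow = TRUE)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# inverted dropout; returns list(out, mask); identity when rate == 0
dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  keep <- 1 - rate
  mask <- matrix(stats::rbinom(length(X), 1, keep) / keep, nrow(X), ncol(X))
  list(out = X * mask, mask = mask)
}
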