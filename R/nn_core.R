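# Internal numeric primitives shared by the attention, fusion and model code.
# All layers use the row convention: one token per row, Y = X %*% W + b.

#' Row-wise softmax under an additive {0, -Inf} mask
#'
#' Rows whose entries are all -Inf (no visible position) return an all-zero
#' row rather than NaN; callers that must treat that as an error check first.
#'
#' @param S numeric matrix of (already masked) attention scores.
#' @return matrix of the same shape; each row sums to 1 over visible entries,
#'   or is identically 0 when every entry is masked.
#' @keywords internal
#' @noRd
softmax_masked <- function(S) {
  m <- apply(S, 1L, max)
  m[!is.finite(m)] <- 0
  E <- exp(S - m)          # recycles m down columns (length n = nrow)
  E[!is.finite(E)] <- 0    # exp(-Inf - m) is 0 already; guard NaN
  z <- rowSums(E)
  E / ifelse(z > 0, z, 1)
}

# Backward through row softmax: given weights W = softmax(S) and upstream dW.
softmax_masked_bwd <- function(dW, W) {
  W * (dW - rowSums(dW * W))
}

# Layer normalization over the feature (column) dimension, per row.
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, "*")
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2L, g, "*")
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dX = dX, dg = dg, db = db)
}

relu <- function(x) pmax(x, 0)

# Glorot/Xavier uniform initialisation for a d_in x d_out weight matrix.
glorot <- function(d_in, d_out) {
  r <- sqrt(6 / (d_in + d_out))
  matrix(stats::runif(d_in * d_out, -r, r), d_in, d_out)
}

# Add a bias (length-d vector) to every row of X.
add_bias <- function(X, b) sweep(X, 2L, b, "+")

#' Sinusoidal positional encodings
#'
#' Fixed (non-learned) encodings: even feature columns carry
#' sin(pos / 10000^(2i/d)), odd columns the matching cosine. Position 0 is
#' therefore all zeros on the sine columns and all ones on the cosine columns.
#'
#' @param n_positions number of positions (rows), positions 0..n_positions-1.
#' @param d_model embedding width (columns).
#' @return an \code{n_positions x d_model} matrix.
#' @export
positional_encoding <- function(n_positions, d_model) {
  stopifnot(n_positions >= 1, d_model >= 2)
  pos <- 0:(n_positions - 1)
  pe <- matrix(0, n_positions, d_model)
  half <- seq_len(ceiling(d_model / 2)) - 1L
  freq <- 1 / (10000^(2 * half / d_model))
  ang <- outer(pos, freq)
  pe[, 2 * half + 1] <- sin(ang)
  odd <- 2 * half + 2
  keep <- odd <= d_model
  pe[, odd[keep]] <- cos(ang[, keep, drop = FALSE])
  pe
}
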