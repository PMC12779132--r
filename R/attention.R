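#' Attention block configuration
#'
#' @param d_model embedding width; must equal \code{n_heads * d_k}.
#' @param n_heads number of parallel attention heads.
#' @param ffn_hidden hidden width of the position-wise feed-forward sub-layer.
#' @param ln_epsilon layer-normalization variance floor.
#' @return an object of class \code{attention_config}.
#' @export
attention_config <- function(d_model = 64L, n_heads = 4L,
                             ffn_hidden = 2L * d_model, ln_epsilon = 1e-5) {
  d_model <- as.integer(d_model); n_heads <- as.integer(n_heads)
  if (d_model < 1L || n_heads < 1L) stop("d_model and n_heads must be positive")
  if (d_model %% n_heads != 0L)
    stop("config error: d_model must be a multiple of n_heads")
  structure(list(d_model = d_model, n_heads = n_heads,
                 d_k = d_model %/% n_heads,
                 ffn_hidden = as.integer(ffn_hidden),
                 ln_epsilon = ln_epsilon),
            class = "attention_config")
}

#' Masked scaled dot-product attention
#'
#' Computes \code{softmax(Q K' / sqrt(d_k) + mask) V}. The additive mask is
#' over \{0, -Inf\}; masked positions receive exactly zero weight (the softmax
#' is renormalized over visible entries only), so each output row is a convex
#' combination of the visible V rows.
#'
#' @param Q,K n x d_k and m x d_k query/key matrices.
#' @param V m x d_v value matrix.
#' @param mask n x m additive mask over \{0, -Inf\}; every row must keep at
#'   least one visible entry.
#' @param return_weights also return the attention weight matrix.
#' @return the n x d_v output matrix, or (with \code{return_weights}) a list
#'   with elements \code{output} and \code{weights}.
#' @export
masked_attention <- function(Q, K, V, mask = NULL, return_weights = FALSE) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("shape error: Q and K widths differ")
  if (nrow(K) != nrow(V)) stop("shape error: K and V row counts differ")
  if (is.null(mask)) mask <- matrix(0, nrow(Q), nrow(K))
  mask <- as.matrix(mask)
  if (nrow(mask) != nrow(Q) || ncol(mask) != nrow(K))
    stop("shape error: mask must be nrow(Q) x nrow(K)")
  bad <- !(mask == 0 | mask == -Inf)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) stop("mask entries must be 0 or -Inf")
  S <- (Q %*% t(K)) / sqrt(ncol(K)) + mask
  if (any(apply(S, 1L, function(r) all(!is.finite(r)))))
    stop("degenerate-mask: a query row has no visible key")
  W <- softmax_masked(S)
  out <- W %*% V
  if (return_weights) list(output = out, weights = W) else out
}

#' Initialize the parameters of one attention block
#'
#' Projection weights (query/key/value/output), layer-norm gains/biases and
#' the feed-forward weights of a single pre-norm transformer block. Draws from
#' the current RNG state; seed upstream for reproducibility.
#'
#' @param config an \code{\link{attention_config}}.
#' @return a named list of parameter matrices/vectors.
#' @export
init_attention_block <- function(config) {
  d <- config$d_model; f <- config$ffn_hidden
  list(ln1_g = rep(1, d), ln1_b = rep(0, d),
       Wq = glorot(d, d), bq = rep(0, d),
       Wk = glorot(d, d), bk = rep(0, d),
       Wv = glorot(d, d), bv = rep(0, d),
       Wo = glorot(d, d), bo = rep(0, d),
       ln2_g = rep(1, d), ln2_b = rep(0, d),
       W1 = glorot(d, f), b1 = rep(0, f),
       W2 = glorot(f, d), b2 = rep(0, d))
}

# Multi-head attention on a single sequence pair of plain matrices.
# Xq: nq x d, Xkv: nk x d; mask: nq x nk additive. Optional LoRA adapters on
# the query and value projections (list(q = , v = ) of lora_adapter).
# Returns list(output, weights = list per head).
mha_single <- function(Xq, Xkv, p, n_heads, mask, lora = NULL,
                       return_weights = FALSE) {
  d <- ncol(Xq); dk <- d %/% n_heads
  Q <- add_bias(Xq %*% p$Wq, p$bq)
  K <- add_bias(Xkv %*% p$Wk, p$bk)
  V <- add_bias(Xkv %*% p$Wv, p$bv)
  if (!is.null(lora)) {
    if (!is.null(lora$q)) Q <- Q + (Xq %*% t(lora$q$A_lr)) %*% t(lora$q$B_lr)
    if (!is.null(lora$v)) V <- V + (Xkv %*% t(lora$v$A_lr)) %*% t(lora$v$B_lr)
  }
  O <- matrix(0, nrow(Xq), d)
  wts <- if (return_weights) vector("list", n_heads) else NULL
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    S <- (Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE])) / sqrt(dk) + mask
    A <- softmax_masked(S)
    if (return_weights) wts[[h]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- add_bias(O %*% p$Wo, p$bo)
  # a query row with no visible key contributes a zero attention term
  dead <- rowSums(is.finite(mask)) == 0L
  if (any(dead)) out[dead, ] <- 0
  list(output = out, weights = wts)
}

#' Multi-head causal transformer block
#'
#' One pre-norm residual block: LayerNorm, multi-head self-attention under the
#' causal mask, residual add, LayerNorm, position-wise feed-forward, residual
#' add. The causality contract: the output at position i is invariant to any
#' perturbation of input tokens at positions j > i.
#'
#' @param X a \code{\link{feature_sequence}} (or bare n x d_model matrix).
#' @param config an \code{\link{attention_config}} with matching d_model.
#' @param params a parameter list from \code{\link{init_attention_block}}.
#' @param mask additive n x n mask; defaults to \code{build_causal_mask(n)}.
#'   Pass a zero matrix to recover a standard (unmasked) block.
#' @return a \code{feature_sequence} of the same shape, tags and positions.
#' @export
multi_head_causal_block <- function(X, config, params, mask = NULL) {
  V <- seq_values(X)
  if (ncol(V) != config$d_model)
    stop("config error: input width ", ncol(V), " != d_model ", config$d_model)
  n <- nrow(V)
  if (is.null(mask)) mask <- build_causal_mask(n)
  H1 <- ln_fwd(V, params$ln1_g, params$ln1_b, config$ln_epsilon)$Y
  att <- mha_single(H1, H1, params, config$n_heads, mask)
  X2 <- V + att$output
  H2 <- ln_fwd(X2, params$ln2_g, params$ln2_b, config$ln_epsilon)$Y
  FF <- add_bias(relu(add_bias(H2 %*% params$W1, params$b1)) %*% params$W2,
                 params$b2)
  out <- X2 + FF
  if (inherits(X, "feature_sequence"))
    feature_sequence(out, X$tags, X$positions)
  else out
}
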