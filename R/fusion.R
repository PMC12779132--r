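#' Layer normalization
#'
#' Row-wise normalization over the feature dimension followed by a learned
#' affine map: \code{gamma * (x - mean) / sqrt(var + eps) + beta}.
#'
#' @param X a \code{feature_sequence} or n x d matrix.
#' @param gamma,beta length-d gain and bias vectors; default identity map.
#' @param eps variance floor.
#' @return object of the same type as \code{X}.
#' @export
layer_norm <- function(X, gamma = NULL, beta = NULL, eps = 1e-5) {
  V <- seq_values(X)
  if (is.null(gamma)) gamma <- rep(1, ncol(V))
  if (is.null(beta)) beta <- rep(0, ncol(V))
  Y <- ln_fwd(V, gamma, beta, eps)$Y
  if (inherits(X, "feature_sequence")) feature_sequence(Y, X$tags, X$positions) else Y
}

#' Position-wise feed-forward network
#'
#' Applies \code{W2' ReLU(W1' x + b1) + b2} to every token independently
#' (row convention: \code{relu(X W1 + b1) W2 + b2}).
#'
#' @param X a \code{feature_sequence} or n x d matrix.
#' @param params list with \code{W1} (d x hidden), \code{b1}, \code{W2}
#'   (hidden x d_out), \code{b2}.
#' @return object of the same type as \code{X}.
#' @export
feed_forward <- function(X, params) {
  V <- seq_values(X)
  if (ncol(V) != nrow(params$W1)) stop("shape error: input width != nrow(W1)")
  Y <- add_bias(relu(add_bias(V %*% params$W1, params$b1)) %*% params$W2,
                params$b2)
  if (inherits(X, "feature_sequence")) feature_sequence(Y, X$tags, X$positions) else Y
}

#' Initialize the parameters of one cross-modal fusion block
#'
#' Projection weights for the constrained cross-modal multi-head attention,
#' the post-attention and post-feed-forward layer norms, and the feed-forward
#' weights. Draws from the current RNG state.
#'
#' @param config an \code{\link{attention_config}}.
#' @return named list of parameters.
#' @export
init_cross_modal_block <- function(config) {
  d <- config$d_model; f <- config$ffn_hidden
  list(Wq = glorot(d, d), bq = rep(0, d),
       Wk = glorot(d, d), bk = rep(0, d),
       Wv = glorot(d, d), bv = rep(0, d),
       Wo = glorot(d, d), bo = rep(0, d),
       ln_a_g = rep(1, d), ln_a_b = rep(0, d),
       W1 = glorot(d, f), b1 = rep(0, f),
       W2 = glorot(f, d), b2 = rep(0, d),
       ln_f_g = rep(1, d), ln_f_b = rep(0, d))
}

#' Constrained cross-modal multi-head attention (post-norm)
#'
#' Computes \code{LayerNorm(X_q + Concat(head_1..head_h) W_O)} where every
#' head attends from the query sequence to the key/value sequence under the
#' allowed-pair modality mask: attention mass on any (query modality, key
#' modality) pair outside the policy's allowed set P is exactly zero. A query
#' token whose modality has no allowed key modality receives a zero attention
#' term, so the block degrades gracefully to \code{LayerNorm(X_q)}.
#'
#' @param X_q,X_kv \code{\link{feature_sequence}} objects with d_model
#'   columns (query side and key/value side; they may be the same sequence).
#' @param policy a \code{\link{modality_policy}}.
#' @param config an \code{\link{attention_config}}.
#' @param params parameters from \code{\link{init_cross_modal_block}}.
#' @param return_weights also return the per-head attention weight matrices.
#' @return a \code{feature_sequence} with \code{X_q}'s shape/tags, or (with
#'   \code{return_weights}) a list \code{(output, weights)}.
#' @export
cross_modal_multihead <- function(X_q, X_kv, policy, config, params,
                                  return_weights = FALSE) {
  Vq <- seq_values(X_q); Vk <- seq_values(X_kv)
  if (ncol(Vq) != config$d_model || ncol(Vk) != config$d_model)
    stop("config error: sequences must have d_model columns")
  mask <- build_allowed_mask(policy, X_q$tags, X_kv$tags)
  att <- mha_single(Vq, Vk, params, config$n_heads, mask,
                    return_weights = return_weights)
  Y <- ln_fwd(Vq + att$output, params$ln_a_g, params$ln_a_b,
              config$ln_epsilon)$Y
  out <- feature_sequence(Y, X_q$tags, X_q$positions)
  if (return_weights) list(output = out, weights = att$weights) else out
}
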