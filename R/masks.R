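#' Build the additive causal attention mask
#'
#' Entry (i, j) is 0 when j <= i (a token may attend to itself and earlier
#' positions) and -Inf when j > i, so future positions receive exactly zero
#' attention weight after the softmax.
#'
#' @param n positive integer, number of tokens.
#' @return an n x n matrix over \{0, -Inf\} with n(n-1)/2 masked entries.
#' @examples
#' build_causal_mask(3)
#' @export
build_causal_mask <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != as.integer(n))
    stop("invalid size: n must be a positive integer")
  n <- as.integer(n)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- -Inf
  M
}

#' Modality pairing policy for constrained cross-modal attention
#'
#' The whitelist P of ordered (query-modality, key-modality) pairs that are
#' permitted to exchange attention. Attention between any pair outside P is
#' masked to exactly zero weight.
#'
#' @param pairs list of length-2 character vectors, each
#'   \code{c(query_modality, key_modality)}; may be empty (no pair allowed).
#' @param query_modalities,key_modalities the modality universes A and B; the
#'   defaults cover all three modalities.
#' @return an object of class \code{modality_policy}.
#' @export
modality_policy <- function(pairs,
                            query_modalities = c("structured", "text", "image"),
                            key_modalities = c("structured", "text", "image")) {
  pairs <- lapply(pairs, as.character)
  for (p in pairs) {
    if (length(p) != 2L) stop("each pair must be (query, key)")
    if (!(p[1] %in% query_modalities) || !(p[2] %in% key_modalities))
      stop("pair outside the declared modality sets: ", paste(p, collapse = "->"))
  }
  structure(list(A = query_modalities, B = key_modalities, P = pairs),
            class = "modality_policy")
}

#' Default allowed-pair policy for the three-modality model
#'
#' Text and image exchange attention symmetrically; the structured token reads
#' from both text and image. The policy is a model configuration knob, not a
#' learned quantity.
#'
#' @return a \code{modality_policy}.
#' @export
default_policy <- function() {
  modality_policy(list(c("text", "image"), c("image", "text"),
                       c("structured", "text"), c("structured", "image")))
}

# All (query, key) modality pairs allowed: unconstrained cross-attention.
complete_policy <- function() {
  mods <- c("structured", "text", "image")
  modality_policy(do.call(c, lapply(mods, function(a)
    lapply(mods, function(b) c(a, b)))))
}

#' Build the additive allowed-pair mask over token pairs
#'
#' Entry (i, j) is 0 iff the (query tag i, key tag j) modality pair is in the
#' policy's allowed set P, else -Inf.
#'
#' @param policy a \code{\link{modality_policy}}.
#' @param query_tags,key_tags character vectors of per-token modality tags.
#' @return an \code{length(query_tags) x length(key_tags)} additive mask.
#' @export
build_allowed_mask <- function(policy, query_tags, key_tags) {
  stopifnot(inherits(policy, "modality_policy"))
  bad_q <- setdiff(unique(query_tags), policy$A)
  bad_k <- setdiff(unique(key_tags), policy$B)
  if (length(bad_q) || length(bad_k))
    stop("tag outside policy modality sets: ",
         paste(c(bad_q, bad_k), collapse = ", "))
  allowed <- matrix(FALSE, length(policy$A), length(policy$B),
                    dimnames = list(policy$A, policy$B))
  for (p in policy$P) allowed[p[1], p[2]] <- TRUE
  M <- matrix(-Inf, length(query_tags), length(key_tags))
  M[allowed[cbind(rep(match(query_tags, policy$A), times = length(key_tags)),
                  rep(match(key_tags, policy$B), each = length(query_tags)))]] <- 0
  M
}
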