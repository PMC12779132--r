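#' Embedding configuration for the modality encoders
#'
#' @param d_model unified embedding width.
#' @param patch_size side length p of the square image patches; must divide
#'   the image height and width.
#' @param vocab_size text vocabulary size (token ids are 0-based).
#' @param max_positions largest supported assembled sequence length.
#' @return an object of class \code{embedding_config}.
#' @export
embedding_config <- function(d_model = 64L, patch_size = 4L, vocab_size = 32L,
                             max_positions = 512L) {
  if (vocab_size < 2L) stop("vocab_size must be at least 2")
  structure(list(d_model = as.integer(d_model),
                 patch_size = as.integer(patch_size),
                 vocab_size = as.integer(vocab_size),
                 max_positions = as.integer(max_positions)),
            class = "embedding_config")
}

#' Initialize modality embedding parameters
#'
#' One linear projection per modality: a patch projection for images, a
#' lookup table for text tokens, and a single linear map for the structured
#' vector. Draws from the current RNG state.
#'
#' @param config an \code{\link{embedding_config}}.
#' @param structured_dim length of the structured feature vector.
#' @return named list: \code{W_img}, \code{b_img}, \code{E_tok},
#'   \code{W_str}, \code{b_str}.
#' @export
init_embedding_params <- function(config, structured_dim) {
  d <- config$d_model; pp <- config$patch_size^2
  list(W_img = glorot(pp, d), b_img = rep(0, d),
       E_tok = matrix(stats::rnorm(config$vocab_size * d, sd = 0.05),
                      config$vocab_size, d),
       W_str = glorot(structured_dim, d), b_str = rep(0, d))
}

# Flatten an H x W image into raster-ordered p x p patch rows:
# one row per patch, patches ordered left-to-right then top-to-bottom,
# pixels within a patch in column-major order of the p x p sub-grid.
image_to_patches <- function(image, p) {
  H <- nrow(image); W <- ncol(image)
  if (H %% p != 0L || W %% p != 0L)
    stop("patching error: image dims (", H, "x", W, ") not divisible by patch size ", p)
  gr <- H %/% p; gc <- W %/% p
  out <- matrix(0, gr * gc, p * p)
  k <- 0L
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      k <- k + 1L
      out[k, ] <- as.vector(image[((i - 1L) * p + 1L):(i * p),
                                  ((j - 1L) * p + 1L):(j * p)])
    }
  }
  out
}

#' Embed an image as a sequence of linearly projected patches
#'
#' Splits the image into raster-ordered p x p patches and applies one shared
#' linear projection per flattened patch.
#'
#' @param image H x W numeric matrix; H and W divisible by the patch size.
#' @param config an \code{\link{embedding_config}}.
#' @param params embedding parameters (\code{\link{init_embedding_params}}).
#' @return a \code{\link{feature_sequence}} of (H/p)(W/p) tokens tagged
#'   \code{"image"}.
#' @export
embed_image <- function(image, config, params) {
  P <- image_to_patches(as.matrix(image), config$patch_size)
  feature_sequence(add_bias(P %*% params$W_img, params$b_img),
                   rep("image", nrow(P)))
}

#' Embed a text token-id sequence via table lookup
#'
#' @param tokens integer vector of 0-based token ids, all < vocab_size. An
#'   empty vector returns \code{NULL} (absent modality).
#' @inheritParams embed_image
#' @return a \code{feature_sequence} tagged \code{"text"}, or \code{NULL}.
#' @export
embed_text <- function(tokens, config, params) {
  if (length(tokens) == 0L) return(NULL)
  tokens <- as.integer(tokens)
  if (any(tokens < 0L | tokens >= config$vocab_size))
    stop("vocab error: token id outside [0, ", config$vocab_size, ")")
  feature_sequence(params$E_tok[tokens + 1L, , drop = FALSE],
                   rep("text", length(tokens)))
}

#' Embed the structured feature vector as a single token
#'
#' @param vector numeric structured-feature vector.
#' @inheritParams embed_image
#' @return a one-token \code{feature_sequence} tagged \code{"structured"}.
#' @export
embed_structured <- function(vector, params) {
  v <- matrix(as.numeric(vector), 1L)
  if (ncol(v) != nrow(params$W_str))
    stop("shape error: structured vector length ", ncol(v),
         " != projection input ", nrow(params$W_str))
  feature_sequence(add_bias(v %*% params$W_str, params$b_str), "structured")
}

#' Assemble per-modality sequences into one positioned sequence
#'
#' Concatenates the parts in canonical modality order (structured, text,
#' image), renumbers positions 0..n-1 and adds fixed sinusoidal positional
#' encodings. \code{NULL} parts (absent modalities) contribute no tokens.
#'
#' @param parts list of \code{feature_sequence} objects (or \code{NULL}s).
#' @param config an \code{\link{embedding_config}} (for d_model and the
#'   position budget).
#' @return a single \code{feature_sequence}.
#' @export
assemble_sequence <- function(parts, config) {
  parts <- Filter(Negate(is.null), parts)
  if (length(parts) == 0L) stop("empty-case error: all modalities absent")
  ord <- order(match(vapply(parts, function(p) p$tags[1], ""),
                     c("structured", "text", "image")))
  parts <- parts[ord]
  vals <- do.call(rbind, lapply(parts, function(p) p$values))
  tags <- do.call(c, lapply(parts, function(p) p$tags))
  n <- nrow(vals)
  if (n > config$max_positions) stop("sequence exceeds max_positions")
  pe <- positional_encoding(n, config$d_model)
  feature_sequence(vals + pe, tags, 0:(n - 1L))
}
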