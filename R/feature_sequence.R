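#' Ordered multimodal token sequence
#'
#' The currency between all network blocks: an n x d matrix of token
#' embeddings plus a per-token modality tag and a 0-based position index.
#'
#' @param values numeric n x d matrix, one row per token; all entries finite.
#' @param tags character vector of length n; each entry one of
#'   \code{"structured"}, \code{"text"}, \code{"image"}.
#' @param positions integer vector of length n, strictly increasing, 0-based.
#'   Defaults to \code{0:(n-1)}.
#' @return an object of class \code{feature_sequence} with fields
#'   \code{values}, \code{tags}, \code{positions}.
#' @export
feature_sequence <- function(values, tags, positions = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stop("feature_sequence needs at least one token")
  if (!all(is.finite(values))) stop("feature_sequence values must be finite")
  tags <- as.character(tags)
  if (length(tags) != nrow(values)) stop("one tag per token required")
  ok <- tags %in% c("structured", "text", "image")
  if (!all(ok)) stop("unknown modality tag: ", paste(unique(tags[!ok]), collapse = ", "))
  if (is.null(positions)) positions <- seq_len(nrow(values)) - 1L
  positions <- as.integer(positions)
  if (length(positions) != nrow(values)) stop("one position per token required")
  if (any(diff(positions) <= 0L) && length(positions) > 1L)
    stop("positions must be strictly increasing")
  structure(list(values = values, tags = tags, positions = positions),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %d tokens x %d dims (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$tags)), table(x$tags)),
                    collapse = ", ")))
  invisible(x)
}

# Accept either a feature_sequence or a bare matrix; return the matrix.
seq_values <- function(x) {
  if (inherits(x, "feature_sequence")) x$values else as.matrix(x)
}

#' One multimodal case record
#'
#' A single sample: an image grid in [0,1], a token-id text sequence, a
#' numeric structured-feature vector, a binary label vector and a 3-level
#' severity label. Any modality may be absent (\code{NULL}) but not all.
#'
#' @param case_id character identifier.
#' @param image H x W numeric matrix with entries in [0,1], or \code{NULL}.
#' @param text integer vector of 0-based token ids, or \code{NULL}.
#' @param structured numeric vector, or \code{NULL}.
#' @param labels binary (0/1) vector of length L.
#' @param severity one of \code{"mild"}, \code{"moderate"}, \code{"severe"}.
#' @return an object of class \code{case_record}.
#' @export
case_record <- function(case_id, image = NULL, text = NULL, structured = NULL,
                        labels, severity) {
  if (is.null(image) && is.null(text) && is.null(structured))
    stop("at least one modality must be present")
  if (!is.null(image)) {
    image <- as.matrix(image)
    if (any(image < 0 | image > 1)) stop("image intensities must lie in [0,1]")
  }
  if (!is.null(text)) {
    text <- as.integer(text)
    if (any(text < 0L)) stop("token ids must be non-negative")
  }
  if (!is.null(structured)) structured <- as.numeric(structured)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  severity <- match.arg(severity, c("mild", "moderate", "severe"))
  structure(list(case_id = as.character(case_id), image = image, text = text,
                 structured = structured, labels = labels, severity = severity),
            class = "case_record")
}

# Which modalities a record carries, in canonical order.
record_modalities <- function(rec) {
  c("structured", "text", "image")[c(!is.null(rec$structured),
                                     !is.null(rec$text) && length(rec$text) > 0L,
                                     !is.null(rec$image))]
}
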