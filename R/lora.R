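#' Low-rank adaptation (LoRA) adapter
#'
#' A frozen base weight W0 (d_out x d_in) plus a trainable rank-r update
#' Delta W = B A, with B (d_out x r) initialized to zero — so the adapted map
#' equals the base map exactly at initialization — and A (r x d_in) randomly
#' initialized. Only B and A are updated by optimization; W0 is never touched.
#'
#' @param W0 d_out x d_in frozen base matrix.
#' @param rank adapter rank r; 1 <= r <= min(d_in, d_out) (the useful
#'   low-rank regime is r much smaller than the bound).
#' @param A_lr,B_lr optional explicit factor matrices (r x d_in and
#'   d_out x r); defaults: A_lr ~ N(0, 0.02^2), B_lr = 0.
#' @return an object of class \code{lora_adapter}.
#' @export
lora_adapter <- function(W0, rank, A_lr = NULL, B_lr = NULL) {
  W0 <- as.matrix(W0)
  d_out <- nrow(W0); d_in <- ncol(W0)
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(d_in, d_out))
    stop("rank must satisfy 1 <= r <= min(d_in, d_out)")
  if (is.null(A_lr)) A_lr <- matrix(stats::rnorm(rank * d_in, sd = 0.02), rank, d_in)
  if (is.null(B_lr)) B_lr <- matrix(0, d_out, rank)
  A_lr <- as.matrix(A_lr); B_lr <- as.matrix(B_lr)
  if (nrow(A_lr) != rank || ncol(A_lr) != d_in) stop("A_lr must be r x d_in")
  if (nrow(B_lr) != d_out || ncol(B_lr) != rank) stop("B_lr must be d_out x r")
  structure(list(W0 = W0, B_lr = B_lr, A_lr = A_lr, rank = rank),
            class = "lora_adapter")
}

#' Adapted forward pass h = W0 x + B (A x)
#'
#' Computed through the low-rank factors without materializing Delta W.
#'
#' @param adapter a \code{\link{lora_adapter}}.
#' @param x input: a length-d_in vector or a d_in-column matrix of row
#'   vectors (each row mapped independently).
#' @return the adapted output, same orientation as the input.
#' @export
lora_forward <- function(adapter, x) {
  if (is.matrix(x)) {
    if (ncol(x) != ncol(adapter$W0)) stop("shape error: x width != d_in")
    x %*% t(adapter$W0) + (x %*% t(adapter$A_lr)) %*% t(adapter$B_lr)
  } else {
    if (length(x) != ncol(adapter$W0)) stop("shape error: length(x) != d_in")
    drop(adapter$W0 %*% x + adapter$B_lr %*% (adapter$A_lr %*% x))
  }
}

#' Fold the low-rank update into the base weight
#'
#' @param adapter a \code{\link{lora_adapter}}.
#' @return the merged d_out x d_in matrix \code{W0 + B_lr A_lr}; a forward
#'   pass with it matches \code{\link{lora_forward}} up to rounding.
#' @export
merge_adapter <- function(adapter) {
  adapter$W0 + adapter$B_lr %*% adapter$A_lr
}

#' Trainable parameter count of a LoRA adapter
#'
#' @param adapter a \code{\link{lora_adapter}}.
#' @return \code{r * (d_in + d_out)} — the entries of A and B; W0 is frozen.
#' @export
lora_param_count <- function(adapter) {
  adapter$rank * (ncol(adapter$W0) + nrow(adapter$W0))
}

#' Save / load model adapters
#'
#' Adapters are written as a JSON manifest (shapes, rank, attachment names)
#' plus one plain-text matrix file per factor, so the archive is portable and
#' diff-able.
#'
#' @param adapters named list of \code{lora_adapter} objects (names are the
#'   attachment points, e.g. \code{"causal.1.q"}).
#' @param path directory to write to / read from (created if needed).
#' @return \code{save_adapters} returns \code{path} invisibly;
#'   \code{load_adapters} returns the named adapter list.
#' @export
save_adapters <- function(adapters, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(adapters, function(a)
    list(rank = a$rank, d_out = nrow(a$W0), d_in = ncol(a$W0)))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  for (nm in names(adapters)) {
    a <- adapters[[nm]]
    for (part in c("W0", "B_lr", "A_lr"))
      utils::write.table(a[[part]],
                         file.path(path, paste0(nm, ".", part, ".tsv")),
                         row.names = FALSE, col.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' @rdname save_adapters
#' @export
load_adapters <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  out <- lapply(names(manifest), function(nm) {
    rd <- function(part)
      as.matrix(utils::read.table(file.path(path, paste0(nm, ".", part, ".tsv")),
                                  sep = "\t"))
    a <- rd("W0"); dimnames(a) <- NULL
    b <- rd("B_lr"); dimnames(b) <- NULL
    aa <- rd("A_lr"); dimnames(aa) <- NULL
    lora_adapter(a, manifest[[nm]]$rank, A_lr = aa, B_lr = b)
  })
  names(out) <- names(manifest)
  out
}
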