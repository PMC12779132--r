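# Task losses for the multi-task objective: the primary coding loss plus the
# two auxiliary tasks (cross-modal contrastive alignment, severity).

# Row softmax of a plain logit matrix (numerically stabilized, no mask).
softmax_rows <- function(Z) {
  m <- apply(Z, 1L, max)
  E <- exp(Z - m)
  E / rowSums(E)
}

# Mean cross-entropy of integer class labels (1-based) under logits.
cross_entropy <- function(logits, classes) {
  P <- softmax_rows(logits)
  -mean(log(pmax(P[cbind(seq_len(nrow(P)), classes)], 1e-300)))
}

l2_normalize_rows <- function(X) {
  nrm <- sqrt(rowSums(X * X))
  X / pmax(nrm, 1e-12)
}

#' Symmetric cross-modal InfoNCE contrastive loss
#'
#' Aligns the per-modality embeddings of the same case while pushing apart
#' different cases. For every unordered modality pair and both directions,
#' case i's embedding must match its counterpart among all N candidates under
#' cosine similarity scaled by 1/temperature; the per-direction cross-entropy
#' losses are averaged.
#'
#' @param embeddings list (length >= 2) of N x d matrices, row-aligned by
#'   case; one matrix per modality.
#' @param temperature softmax temperature tau > 0.
#' @return scalar loss (mean over all modality pairs and directions).
#' @export
contrastive_loss <- function(embeddings, temperature = 0.1) {
  if (length(embeddings) < 2L) stop("need at least two modality embeddings")
  N <- nrow(embeddings[[1]])
  if (N < 2L) stop("insufficient-batch: contrastive loss needs N >= 2")
  if (!all(vapply(embeddings, nrow, 0L) == N))
    stop("embeddings must be row-aligned by case")
  U <- lapply(embeddings, l2_normalize_rows)
  total <- 0; ndir <- 0L
  for (a in seq_along(U)) for (b in seq_along(U)) {
    if (a >= b) next
    C <- (U[[a]] %*% t(U[[b]])) / temperature
    total <- total + cross_entropy(C, seq_len(N)) + cross_entropy(t(C), seq_len(N))
    ndir <- ndir + 2L
  }
  total / ndir
}

#' Auxiliary severity-prediction loss
#'
#' Mean cross-entropy of the three severity categories (mild, moderate,
#' severe), treated as unordered classes.
#'
#' @param logits N x 3 matrix of severity logits.
#' @param severity integer labels in \{0, 1, 2\} (or the factor/character
#'   levels mild/moderate/severe).
#' @return scalar loss.
#' @export
severity_loss <- function(logits, severity) {
  logits <- as.matrix(logits)
  if (ncol(logits) != 3L) stop("severity logits must have 3 columns")
  if (is.character(severity) || is.factor(severity))
    severity <- match(as.character(severity), c("mild", "moderate", "severe")) - 1L
  severity <- as.integer(severity)
  if (any(is.na(severity)) || any(severity < 0L | severity > 2L))
    stop("severity labels must lie in {0, 1, 2}")
  cross_entropy(logits, severity + 1L)
}

#' One task of the multi-task objective
#'
#' @param name task name (\code{"coding"}, \code{"contrastive"},
#'   \code{"severity"}).
#' @param weight non-negative loss weight lambda_k.
#' @param loss_kind descriptive string for reporting.
#' @return an object of class \code{task_spec}.
#' @export
task_spec <- function(name = c("coding", "contrastive", "severity"),
                      weight = 1.0, loss_kind = "cross_entropy") {
  name <- match.arg(name)
  weight <- as.numeric(weight)
  if (!is.finite(weight) || weight < 0) stop("task weight must be finite and >= 0")
  structure(list(name = name, weight = weight, loss_kind = loss_kind),
            class = "task_spec")
}

#' Weighted multi-task total loss
#'
#' \code{sum_k lambda_k * L_k} over the task list. The primary (coding) task
#' must carry positive weight.
#'
#' @param losses numeric vector of per-task losses, aligned with
#'   \code{tasks}.
#' @param tasks list of \code{\link{task_spec}} objects, or a plain numeric
#'   weight vector.
#' @return scalar total loss.
#' @export
total_loss <- function(losses, tasks) {
  w <- if (is.numeric(tasks)) tasks
       else vapply(tasks, function(t) t$weight, 0)
  if (length(w) != length(losses))
    stop("length mismatch between tasks and losses")
  if (!is.numeric(tasks)) {
    nm <- vapply(tasks, function(t) t$name, "")
    if ("coding" %in% nm && w[match("coding", nm)] <= 0)
      stop("primary task weight must be positive")
  }
  sum(w * losses)
}
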