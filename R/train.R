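# Mini-batch training with Adam, early stopping on validation subset
# accuracy, and split evaluation via the five multi-label metrics.

#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param batch_size mini-batch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience: training stops when the
#'   validation subset accuracy has not improved for this many consecutive
#'   epochs; the best-epoch parameters are restored.
#' @param seed mandatory integer seed covering initial shuffling and every
#'   stochastic step.
#' @param verbose print one structured log line per epoch.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(epochs = 40L, batch_size = 32L, lr = 1e-3,
                         patience = 5L, seed = 1L, verbose = FALSE) {
  if (any(c(epochs, batch_size, patience) < 1L) || lr <= 0)
    stop("train_config values must be positive")
  if (is.null(seed)) stop("seed is mandatory")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Convert records to batched tensors, grouped by modality-presence pattern.
# Returns a list of groups: each has B, present, Xs/tok/patches, Y (binary
# matrix), cls (1-based class), sev (0..2), idx (record indices), layout.
dataset_tensors <- function(model, dataset, indices) {
  recs <- dataset$records[indices]
  pres <- vapply(recs, function(r)
    paste0(as.integer(c(!is.null(r$structured),
                        !is.null(r$text) && length(r$text) > 0L,
                        !is.null(r$image))), collapse = ""), "")
  groups <- split(seq_along(recs), pres)
  cfg <- model$config
  lapply(groups, function(gi) {
    rs <- recs[gi]
    present <- c(structured = !is.null(rs[[1]]$structured),
                 text = !is.null(rs[[1]]$text) && length(rs[[1]]$text) > 0L,
                 image = !is.null(rs[[1]]$image))
    n_text <- if (present[["text"]]) length(rs[[1]]$text) else 0L
    n_img <- if (present[["image"]])
      (nrow(rs[[1]]$image) %/% cfg$patch_size) *
      (ncol(rs[[1]]$image) %/% cfg$patch_size) else 0L
    out <- list(B = length(rs), present = present, idx = indices[gi])
    if (present[["structured"]])
      out$Xs <- do.call(rbind, lapply(rs, `[[`, "structured"))
    if (present[["text"]])
      out$tok <- do.call(rbind, lapply(rs, `[[`, "text"))
    if (present[["image"]])
      out$patches <- do.call(rbind, lapply(rs, function(r)
        image_to_patches(r$image, cfg$patch_size)))
    out$Y <- do.call(rbind, lapply(rs, `[[`, "labels"))
    out$cls <- max.col(out$Y, ties.method = "first")
    out$sev <- match(vapply(rs, `[[`, "", "severity"),
                     c("mild", "moderate", "severe")) - 1L
    out$layout <- seq_layout(cfg, present, n_text, n_img)
    out
  })
}

# Slice a tensor group to a subset of its local rows.
slice_group <- function(g, rows) {
  out <- g
  out$B <- length(rows)
  n_img <- if (g$present[["image"]]) nrow(g$patches) %/% g$B else 0L
  if (!is.null(g$Xs)) out$Xs <- g$Xs[rows, , drop = FALSE]
  if (!is.null(g$tok)) out$tok <- g$tok[rows, , drop = FALSE]
  if (!is.null(g$patches)) {
    pr <- as.vector(vapply(rows, function(r) (r - 1L) * n_img + seq_len(n_img),
                           integer(n_img)))
    out$patches <- g$patches[pr, , drop = FALSE]
  }
  out$Y <- g$Y[rows, , drop = FALSE]
  out$cls <- g$cls[rows]
  out$sev <- g$sev[rows]
  out$idx <- g$idx[rows]
  out
}

#' Train the multimodal coding model
#'
#' Optimizes the weighted multi-task objective by mini-batch Adam, evaluating
#' subset accuracy on the validation split after every epoch, stopping when
#' it fails to improve for \code{patience} epochs and restoring the
#' best-epoch parameters. Fully deterministic given the seeds (single
#' threaded).
#'
#' @param model an \code{mm_model} from \code{\link{build_model}}.
#' @param dataset a \code{synthetic_dataset} (or any object with
#'   \code{records} and \code{splits}).
#' @param config a \code{\link{train_config}}.
#' @return a list: \code{model} (with best-epoch parameters),
#'   \code{history} (per-epoch data frame: losses per task, validation
#'   subset accuracy), \code{best_epoch}, \code{stop_reason}.
#' @export
train_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset$splits$train) == 0L || length(dataset$splits$val) == 0L)
    stop("dataset must provide non-empty train and val splits")
  set.seed(config$seed)
  tens_tr <- dataset_tensors(model, dataset, dataset$splits$train)
  tens_va <- dataset_tensors(model, dataset, dataset$splits$val)
  frozen <- frozen_names(model)
  trainable <- setdiff(names(model$params), frozen)
  mstate <- lapply(model$params[trainable], function(x) x * 0)
  vstate <- mstate
  t_step <- 0L
  b1 <- 0.9; b2 <- 0.999; ae <- 1e-8
  hist <- list()
  best_acc <- -Inf; best_params <- model$params; best_epoch <- 0L
  since <- 0L; stop_reason <- "max_epochs"
  for (epoch in seq_len(config$epochs)) {
    # batches within presence groups, order shuffled across groups
    batches <- list()
    for (g in tens_tr) {
      ord <- sample.int(g$B)
      starts <- seq(1L, g$B, by = config$batch_size)
      for (s in starts)
        batches[[length(batches) + 1L]] <-
          list(g = g, rows = ord[s:min(s + config$batch_size - 1L, g$B)])
    }
    batches <- batches[sample.int(length(batches))]
    ep_losses <- c(coding = 0, contrastive = 0, severity = 0)
    ep_total <- 0; nb <- 0L
    for (bt in batches) {
      bb <- slice_group(bt$g, bt$rows)
      lg <- model_loss_grad(model, bb, bt$g$layout)
      t_step <- t_step + 1L
      corr <- sqrt(1 - b2^t_step) / (1 - b1^t_step)
      for (nm in names(lg$grads)) {
        if (nm %in% frozen) next
        gmat <- lg$grads[[nm]]
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * gmat
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * gmat * gmat
        model$params[[nm]] <- model$params[[nm]] -
          config$lr * corr * mstate[[nm]] / (sqrt(vstate[[nm]]) + ae)
      }
      ep_total <- ep_total + lg$total
      ep_losses <- ep_losses + ifelse(is.na(lg$losses), 0, lg$losses)
      nb <- nb + 1L
    }
    val_acc <- .split_subset_accuracy(model, tens_va)
    hist[[epoch]] <- data.frame(epoch = epoch, total = ep_total / nb,
                                coding = ep_losses[["coding"]] / nb,
                                contrastive = ep_losses[["contrastive"]] / nb,
                                severity = ep_losses[["severity"]] / nb,
                                val_subset_accuracy = val_acc)
    if (config$verbose)
      message(sprintf("epoch %d | loss %.4f | val subset acc %.4f",
                      epoch, ep_total / nb, val_acc))
    if (val_acc > best_acc + 1e-12) {
      best_acc <- val_acc; best_params <- model$params
      best_epoch <- epoch; since <- 0L
    } else {
      since <- since + 1L
      if (since >= config$patience) { stop_reason <- "early_stop"; break }
    }
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch,
       stop_reason = stop_reason)
}

# Subset accuracy of argmax predictions over tensor groups.
.split_subset_accuracy <- function(model, tens) {
  hits <- 0L; tot <- 0L
  for (g in tens) {
    fw <- model_forward(model, g, g$layout)
    hits <- hits + sum(max.col(fw$logits, ties.method = "first") == g$cls)
    tot <- tot + g$B
  }
  hits / tot
}

#' Predict label scores for a set of records
#'
#' @param model a (trained) \code{mm_model}.
#' @param dataset dataset holding the records.
#' @param indices record indices to score (default: all).
#' @return list with \code{scores} (N x L softmax probabilities, row order =
#'   \code{indices}), \code{Yhat} (one-hot argmax predictions), \code{Y}
#'   (true labels).
#' @export
predict_model <- function(model, dataset, indices = seq_along(dataset$records)) {
  tens <- dataset_tensors(model, dataset, indices)
  N <- length(indices); L <- model$n_classes
  scores <- matrix(NA_real_, N, L)
  Y <- matrix(NA_integer_, N, L)
  pos <- match(unlist(lapply(tens, `[[`, "idx")), indices)
  off <- 0L
  for (g in tens) {
    fw <- model_forward(model, g, g$layout)
    rows <- pos[off + seq_len(g$B)]
    scores[rows, ] <- softmax_rows(fw$logits)
    Y[rows, ] <- g$Y
    off <- off + g$B
  }
  Yhat <- matrix(0L, N, L)
  Yhat[cbind(seq_len(N), max.col(scores, ties.method = "first"))] <- 1L
  list(scores = scores, Yhat = Yhat, Y = Y)
}

#' Evaluate a trained model on a named split
#'
#' Applies the five multi-label metrics to the model's predictions on the
#' requested split.
#'
#' @param model a trained \code{mm_model}.
#' @param dataset a \code{synthetic_dataset}.
#' @param split one of \code{"train"}, \code{"val"}, \code{"test"}.
#' @return a \code{metrics_report} (see \code{\link{evaluate_all}}).
#' @export
evaluate_model <- function(model, dataset, split = "test") {
  idx <- dataset$splits[[split]]
  if (is.null(idx) || length(idx) == 0L) stop("empty split: ", split)
  pr <- predict_model(model, dataset, idx)
  evaluate_all(pr$Y, pr$scores, pr$Yhat)
}
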