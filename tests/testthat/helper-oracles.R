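# Independent from-definition oracles and small fixture builders. The
# oracles deliberately use naive element loops so they share no code with
# the package implementations they check.

oracle_subset_accuracy <- function(Y, Yhat) {
  hits <- 0
  for (i in seq_len(nrow(Y))) {
    same <- TRUE
    for (j in seq_len(ncol(Y))) if (Y[i, j] != Yhat[i, j]) same <- FALSE
    if (same) hits <- hits + 1
  }
  hits / nrow(Y)
}

oracle_hamming <- function(Y, Yhat) {
  bad <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(ncol(Y)))
    if (Y[i, j] != Yhat[i, j]) bad <- bad + 1
  bad / (nrow(Y) * ncol(Y))
}

oracle_macro_f1 <- function(Y, Yhat) {
  f1s <- numeric(ncol(Y))
  for (j in seq_len(ncol(Y))) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(Y))) {
      if (Y[i, j] == 1 && Yhat[i, j] == 1) tp <- tp + 1
      if (Y[i, j] == 0 && Yhat[i, j] == 1) fp <- fp + 1
      if (Y[i, j] == 1 && Yhat[i, j] == 0) fn <- fn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1s[j] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  }
  mean(f1s)
}

oracle_jaccard_samples <- function(Y, Yhat) {
  js <- numeric(nrow(Y))
  for (i in seq_len(nrow(Y))) {
    tp <- un <- 0
    for (j in seq_len(ncol(Y))) {
      if (Y[i, j] == 1 && Yhat[i, j] == 1) tp <- tp + 1
      if (Y[i, j] == 1 || Yhat[i, j] == 1) un <- un + 1
    }
    js[i] <- if (un > 0) tp / un else 1
  }
  mean(js)
}

# One-vs-rest AUC by exhaustive pair counting (ties count one half).
oracle_macro_auc <- function(Y, S) {
  aucs <- c()
  for (j in seq_len(ncol(Y))) {
    pos <- which(Y[, j] == 1); neg <- which(Y[, j] == 0)
    if (length(pos) == 0 || length(neg) == 0) next
    wins <- 0
    for (p in pos) for (q in neg) {
      if (S[p, j] > S[q, j]) wins <- wins + 1
      else if (S[p, j] == S[q, j]) wins <- wins + 0.5
    }
    aucs <- c(aucs, wins / (length(pos) * length(neg)))
  }
  mean(aucs)
}

# All binary matrices of a given shape, as a list.
all_binary_matrices <- function(N, L) {
  n_bits <- N * L
  lapply(0:(2^n_bits - 1), function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_bits)]
    matrix(bits, N, L)
  })
}

# Reference (unmasked) pre-norm transformer block written independently of
# the package internals: plain softmax self-attention + FFN with residuals.
reference_standard_block <- function(X, config, p) {
  lnorm <- function(M, g, b, eps = config$ln_epsilon) {
    mu <- rowMeans(M); xc <- M - mu
    sg <- sqrt(rowMeans(xc^2) + eps)
    t(t(xc / sg) * g + b)
  }
  plain_softmax <- function(S) {
    E <- exp(S - apply(S, 1, max))
    E / rowSums(E)
  }
  d <- config$d_model; h <- config$n_heads; dk <- d / h
  H1 <- lnorm(X, p$ln1_g, p$ln1_b)
  Q <- t(t(H1 %*% p$Wq) + p$bq)
  K <- t(t(H1 %*% p$Wk) + p$bk)
  V <- t(t(H1 %*% p$Wv) + p$bv)
  O <- matrix(0, nrow(X), d)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    A <- plain_softmax(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  X2 <- X + t(t(O %*% p$Wo) + p$bo)
  H2 <- lnorm(X2, p$ln2_g, p$ln2_b)
  X2 + t(t(pmax(t(t(H2 %*% p$W1) + p$b1), 0) %*% p$W2) + p$b2)
}

# Reference post-norm cross-attention block (no modality constraint).
reference_cross_block <- function(Xq, Xkv, config, p) {
  lnorm <- function(M, g, b, eps = config$ln_epsilon) {
    mu <- rowMeans(M); xc <- M - mu
    sg <- sqrt(rowMeans(xc^2) + eps)
    t(t(xc / sg) * g + b)
  }
  plain_softmax <- function(S) {
    E <- exp(S - apply(S, 1, max))
    E / rowSums(E)
  }
  d <- config$d_model; h <- config$n_heads; dk <- d / h
  Q <- t(t(Xq %*% p$Wq) + p$bq)
  K <- t(t(Xkv %*% p$Wk) + p$bk)
  V <- t(t(Xkv %*% p$Wv) + p$bv)
  O <- matrix(0, nrow(Xq), d)
  for (hh in seq_len(h)) {
    cols <- ((hh - 1) * dk + 1):(hh * dk)
    A <- plain_softmax(Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk))
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  lnorm(Xq + t(t(O %*% p$Wo) + p$bo), p$ln_a_g, p$ln_a_b)
}

# Small multimodal dataset + config for fast end-to-end tests.
tiny_model_config <- function(...) {
  model_config(d_model = 8, n_heads = 2, n_causal_blocks = 1,
               ffn_hidden = 12, patch_size = 2, vocab_size = 8, ...)
}

tiny_dataset <- function(n = 24, seed = 5, n_classes = 2) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    cls <- (i %% n_classes) + 1
    case_record(sprintf("t%03d", i),
                image = matrix(runif(16, (cls - 1) * 0.4, (cls - 1) * 0.4 + 0.3), 4, 4),
                text = sample(0:7, 3, replace = TRUE),
                structured = rnorm(3, mean = 2 * cls),
                labels = as.integer(seq_len(n_classes) == cls),
                severity = sample(c("mild", "moderate", "severe"), 1))
  })
  list(records = recs,
       splits = list(train = 1:round(0.7 * n),
                     val = (round(0.7 * n) + 1):round(0.85 * n),
                     test = (round(0.85 * n) + 1):n))
}

# Random feature sequence of one modality per contiguous slice.
random_sequence <- function(n, d, tags = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tags)) tags <- rep("text", n)
  feature_sequence(matrix(rnorm(n * d), n, d), tags)
}

# Nearest class-centroid accuracy on structured features (reference
# classifier for generator signal checks).
centroid_accuracy <- function(dataset) {
  tr <- dataset$splits$train; te <- dataset$splits$test
  X <- do.call(rbind, lapply(dataset$records, `[[`, "structured"))
  cls <- vapply(dataset$records, function(r) which.max(r$labels), 0L)
  cents <- do.call(rbind, lapply(sort(unique(cls[tr])), function(c)
    colMeans(X[tr[cls[tr] == c], , drop = FALSE])))
  pred <- apply(X[te, , drop = FALSE], 1, function(x)
    which.min(colSums((t(cents) - x)^2)))
  mean(pred == cls[te])
}
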