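# Full network assembly: modality encoders -> per-modality causal encoder
# blocks -> allowed-pair cross-modal fusion -> mean-pooled classifier and
# severity heads, with optional LoRA adapters on the query/value projections.
#
# The forward/backward engine works on "stacked" matrices: a batch of B
# sequences of equal length n is one (B*n) x d matrix with sample-major row
# blocks. Token-parallel layers (linear, layer norm, feed-forward) run as
# single matrix ops; only the attention score/softmax/value step loops over
# samples and heads. Gradients are exact reverse-mode derivatives, verified
# against finite differences in the test suite.

#' Model configuration
#'
#' Architecture hyperparameters plus the three ablation switches. Each
#' switch replaces a module by its degenerate form: \code{causal_mask} off
#' uses an all-zero attention mask, \code{pcma} off replaces fusion by plain
#' concatenation + mean pooling, \code{mtl} off sets the auxiliary task
#' weights to zero.
#'
#' @param d_model embedding width (= n_heads * d_k).
#' @param n_heads attention heads per block.
#' @param n_causal_blocks stacked causal encoder blocks per modality.
#' @param ffn_hidden feed-forward hidden width.
#' @param patch_size image patch side length.
#' @param vocab_size text vocabulary size.
#' @param policy a \code{\link{modality_policy}} for the fusion stage.
#' @param lora_enabled attach LoRA adapters to every attention block's query
#'   and value projections and freeze their base weights.
#' @param lora_rank adapter rank r.
#' @param causal_mask,pcma,mtl ablation switches.
#' @param lambda_coding,lambda_contrastive,lambda_severity task loss weights.
#' @param tau contrastive softmax temperature.
#' @param multilabel use element-wise binary cross-entropy for the coding
#'   loss instead of softmax cross-entropy over mutually exclusive classes.
#' @param ln_epsilon layer-norm variance floor.
#' @return an object of class \code{model_config}.
#' @export
model_config <- function(d_model = 64L, n_heads = 4L, n_causal_blocks = 2L,
                         ffn_hidden = 2L * d_model, patch_size = 4L,
                         vocab_size = 32L, policy = default_policy(),
                         lora_enabled = FALSE, lora_rank = 4L,
                         causal_mask = TRUE, pcma = TRUE, mtl = TRUE,
                         lambda_coding = 1.0, lambda_contrastive = 0.3,
                         lambda_severity = 0.3, tau = 0.1,
                         multilabel = FALSE, ln_epsilon = 1e-5) {
  att <- attention_config(d_model, n_heads, ffn_hidden, ln_epsilon)
  structure(list(att = att, n_causal_blocks = as.integer(n_causal_blocks),
                 patch_size = as.integer(patch_size),
                 vocab_size = as.integer(vocab_size), policy = policy,
                 lora = list(enabled = isTRUE(lora_enabled),
                             rank = as.integer(lora_rank)),
                 switches = list(causal_mask = isTRUE(causal_mask),
                                 pcma = isTRUE(pcma), mtl = isTRUE(mtl)),
                 lambdas = c(coding = lambda_coding,
                             contrastive = lambda_contrastive,
                             severity = lambda_severity),
                 tau = tau, multilabel = isTRUE(multilabel)),
            class = "model_config")
}

# Extract the parameter sub-list of one attention/fusion block by prefix.
block_params <- function(params, prefix) {
  nms <- c("ln1_g", "ln1_b", "Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
           "ln2_g", "ln2_b", "W1", "b1", "W2", "b2",
           "ln_a_g", "ln_a_b", "ln_f_g", "ln_f_b")
  out <- list()
  for (nm in nms) {
    v <- params[[paste0(prefix, ".", nm)]]
    if (!is.null(v)) out[[nm]] <- v
  }
  out
}

lora_block <- function(params, prefix) {
  A_q <- params[[paste0("lora.", prefix, ".q.A")]]
  if (is.null(A_q)) return(NULL)
  list(q = list(A = A_q, B = params[[paste0("lora.", prefix, ".q.B")]]),
       v = list(A = params[[paste0("lora.", prefix, ".v.A")]],
                B = params[[paste0("lora.", prefix, ".v.B")]]))
}

#' Build the full multimodal coding model
#'
#' Initializes all parameters (seeded) for the configured data shape and
#' returns the model object used by \code{\link{train_model}} and
#' \code{\link{evaluate_model}}.
#'
#' @param config a \code{\link{model_config}}.
#' @param n_classes number of label columns L.
#' @param structured_dim structured feature length.
#' @param seed integer seed for parameter initialization.
#' @return an object of class \code{mm_model} with fields \code{config},
#'   \code{params} (flat named list), \code{n_classes},
#'   \code{structured_dim}.
#' @export
build_model <- function(config, n_classes, structured_dim, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  d <- config$att$d_model
  p <- list()
  p[["emb.W_img"]] <- glorot(config$patch_size^2, d)
  p[["emb.b_img"]] <- rep(0, d)
  p[["emb.E_tok"]] <- matrix(stats::rnorm(config$vocab_size * d, sd = 0.05),
                             config$vocab_size, d)
  p[["emb.W_str"]] <- glorot(structured_dim, d)
  p[["emb.b_str"]] <- rep(0, d)
  for (k in seq_len(config_n_blocks(config))) {
    bp <- init_attention_block(config$att)
    for (nm in names(bp)) p[[sprintf("causal.%d.%s", k, nm)]] <- bp[[nm]]
  }
  fp <- init_cross_modal_block(config$att)
  for (nm in names(fp)) p[[paste0("fusion.", nm)]] <- fp[[nm]]
  p[["head.W_cls"]] <- glorot(d, n_classes)
  p[["head.b_cls"]] <- rep(0, n_classes)
  p[["head.W_sev"]] <- glorot(d, 3L)
  p[["head.b_sev"]] <- rep(0, 3L)
  if (config$lora$enabled) {
    r <- config$lora$rank
    for (pref in c(sprintf("causal.%d", seq_len(config_n_blocks(config))), "fusion")) {
      for (side in c("q", "v")) {
        p[[sprintf("lora.%s.%s.A", pref, side)]] <-
          matrix(stats::rnorm(r * d, sd = 0.02), r, d)
        p[[sprintf("lora.%s.%s.B", pref, side)]] <- matrix(0, d, r)
      }
    }
  }
  structure(list(config = config, params = p, n_classes = as.integer(n_classes),
                 structured_dim = as.integer(structured_dim)),
            class = "mm_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_n_blocks <- function(config) config$n_causal_blocks %||% 2L

#' Count model parameters
#'
#' Counts the parameters active under the model's current configuration:
#' with the fusion switch off the (unused) fusion block parameters are
#' excluded, so enabling fusion strictly increases the count.
#'
#' @param model an \code{mm_model}.
#' @param trainable_only count only parameters updated by optimization
#'   (excludes frozen LoRA base weights when adapters are enabled).
#' @return integer parameter count.
#' @export
count_parameters <- function(model, trainable_only = FALSE) {
  nms <- names(model$params)
  if (!model$config$switches$pcma)
    nms <- grep("^(fusion\\.|lora\\.fusion\\.)", nms, value = TRUE,
                invert = TRUE)
  if (trainable_only) nms <- setdiff(nms, frozen_names(model))
  sum(vapply(model$params[nms], length, 0L))
}

# Names of frozen base weights under LoRA adaptation.
frozen_names <- function(model) {
  if (!model$config$lora$enabled) return(character(0))
  prefs <- c(sprintf("causal.%d", seq_len(config_n_blocks(model$config))), "fusion")
  as.vector(outer(prefs, c("Wq", "Wv"), function(a, b) paste0(a, ".", b)))
}

# ---- stacked multi-head self-attention -------------------------------------

self_mha_fwd <- function(X, pp, h, mask, B, n, lora = NULL) {
  d <- ncol(X); dk <- d %/% h; sc <- 1 / sqrt(dk)
  Q <- add_bias(X %*% pp$Wq, pp$bq)
  K <- add_bias(X %*% pp$Wk, pp$bk)
  V <- add_bias(X %*% pp$Wv, pp$bv)
  Uq <- Uv <- NULL
  if (!is.null(lora)) {
    Uq <- X %*% t(lora$q$A); Q <- Q + Uq %*% t(lora$q$B)
    Uv <- X %*% t(lora$v$A); V <- V + Uv %*% t(lora$v$B)
  }
  A <- array(0, c(n, n, h, B))
  O <- matrix(0, B * n, d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * n + 1L):(b * n)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      S <- (Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE])) * sc + mask
      Aw <- softmax_masked(S)
      A[, , hh, b] <- Aw
      O[rows, cols] <- Aw %*% V[rows, cols, drop = FALSE]
    }
  }
  out <- add_bias(O %*% pp$Wo, pp$bo)
  dead <- which(rowSums(is.finite(mask)) == 0L)
  if (length(dead)) {
    dg <- as.vector(outer(dead, (seq_len(B) - 1L) * n, `+`))
    out[dg, ] <- 0
  }
  list(out = out, cache = list(X = X, Q = Q, K = K, V = V, O = O, A = A,
                               Uq = Uq, Uv = Uv, dead = dead))
}

self_mha_bwd <- function(dOut, cache, pp, h, B, n, gr, prefix, lora = NULL,
                         lora_prefix = NULL) {
  d <- ncol(cache$X); dk <- d %/% h; sc <- 1 / sqrt(dk)
  if (length(cache$dead)) {
    dg <- as.vector(outer(cache$dead, (seq_len(B) - 1L) * n, `+`))
    dOut[dg, ] <- 0
  }
  gadd(gr, paste0(prefix, ".Wo"), crossprod(cache$O, dOut))
  gadd(gr, paste0(prefix, ".bo"), colSums(dOut))
  dO <- dOut %*% t(pp$Wo)
  dQ <- matrix(0, B * n, d); dK <- dQ; dV <- dQ
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * n + 1L):(b * n)
    for (hh in seq_len(h)) {
      cols <- ((hh - 1L) * dk + 1L):(hh * dk)
      Aw <- cache$A[, , hh, b]
      if (n == 1L) Aw <- matrix(Aw, 1L, 1L)
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[rows, cols] <- dV[rows, cols, drop = FALSE] + crossprod(Aw, dOb)
      dS <- Aw * (dA - rowSums(dA * Aw))
      dQ[rows, cols] <- dQ[rows, cols, drop = FALSE] +
        dS %*% cache$K[rows, cols, drop = FALSE] * sc
      dK[rows, cols] <- dK[rows, cols, drop = FALSE] +
        crossprod(dS, cache$Q[rows, cols, drop = FALSE]) * sc
    }
  }
  X <- cache$X
  gadd(gr, paste0(prefix, ".Wq"), crossprod(X, dQ))
  gadd(gr, paste0(prefix, ".bq"), colSums(dQ))
  gadd(gr, paste0(prefix, ".Wk"), crossprod(X, dK))
  gadd(gr, paste0(prefix, ".bk"), colSums(dK))
  gadd(gr, paste0(prefix, ".Wv"), crossprod(X, dV))
  gadd(gr, paste0(prefix, ".bv"), colSums(dV))
  dX <- dQ %*% t(pp$Wq) + dK %*% t(pp$Wk) + dV %*% t(pp$Wv)
  if (!is.null(lora)) {
    dUq <- dQ %*% lora$q$B
    gadd(gr, paste0("lora.", lora_prefix, ".q.B"), crossprod(dQ, cache$Uq))
    gadd(gr, paste0("lora.", lora_prefix, ".q.A"), crossprod(dUq, X))
    dX <- dX + dUq %*% lora$q$A
    dUv <- dV %*% lora$v$B
    gadd(gr, paste0("lora.", lora_prefix, ".v.B"), crossprod(dV, cache$Uv))
    gadd(gr, paste0("lora.", lora_prefix, ".v.A"), crossprod(dUv, X))
    dX <- dX + dUv %*% lora$v$A
  }
  dX
}

gadd <- function(gr, name, val) {
  cur <- gr[[name]]
  if (is.null(cur)) assign(name, val, envir = gr)
  else assign(name, cur + val, envir = gr)
}

# ---- encoder / fusion blocks on stacked batches ----------------------------

causal_block_fwd <- function(X, pp, h, mask, B, n, eps, lora = NULL) {
  c1 <- ln_fwd(X, pp$ln1_g, pp$ln1_b, eps)
  att <- self_mha_fwd(c1$Y, pp, h, mask, B, n, lora)
  X2 <- X + att$out
  c2 <- ln_fwd(X2, pp$ln2_g, pp$ln2_b, eps)
  Z1 <- add_bias(c2$Y %*% pp$W1, pp$b1)
  Rl <- relu(Z1)
  Y <- X2 + add_bias(Rl %*% pp$W2, pp$b2)
  list(out = Y, cache = list(c1 = c1, att = att$cache, X2 = X2, c2 = c2,
                             Z1 = Z1, Rl = Rl))
}

causal_block_bwd <- function(dY, cache, pp, h, mask, B, n, gr, prefix,
                             lora = NULL, lora_prefix = NULL) {
  gadd(gr, paste0(prefix, ".W2"), crossprod(cache$Rl, dY))
  gadd(gr, paste0(prefix, ".b2"), colSums(dY))
  dZ1 <- (dY %*% t(pp$W2)) * (cache$Z1 > 0)
  gadd(gr, paste0(prefix, ".W1"), crossprod(cache$c2$Y, dZ1))
  gadd(gr, paste0(prefix, ".b1"), colSums(dZ1))
  l2 <- ln_bwd(dZ1 %*% t(pp$W1), cache$c2, pp$ln2_g)
  gadd(gr, paste0(prefix, ".ln2_g"), l2$dg)
  gadd(gr, paste0(prefix, ".ln2_b"), l2$db)
  dX2 <- dY + l2$dX
  dH1 <- self_mha_bwd(dX2, cache$att, pp, h, B, n, gr, prefix, lora, lora_prefix)
  l1 <- ln_bwd(dH1, cache$c1, pp$ln1_g)
  gadd(gr, paste0(prefix, ".ln1_g"), l1$dg)
  gadd(gr, paste0(prefix, ".ln1_b"), l1$db)
  dX2 + l1$dX
}

fusion_block_fwd <- function(X, pp, h, mask, B, n, eps, lora = NULL) {
  att <- self_mha_fwd(X, pp, h, mask, B, n, lora)
  U <- X + att$out
  ca <- ln_fwd(U, pp$ln_a_g, pp$ln_a_b, eps)
  Z1 <- add_bias(ca$Y %*% pp$W1, pp$b1)
  Rl <- relu(Z1)
  V2 <- ca$Y + add_bias(Rl %*% pp$W2, pp$b2)
  cf <- ln_fwd(V2, pp$ln_f_g, pp$ln_f_b, eps)
  list(out = cf$Y, cache = list(att = att$cache, ca = ca, Z1 = Z1, Rl = Rl,
                                cf = cf))
}

fusion_block_bwd <- function(dZ, cache, pp, h, B, n, gr, lora = NULL) {
  lf <- ln_bwd(dZ, cache$cf, pp$ln_f_g)
  gadd(gr, "fusion.ln_f_g", lf$dg)
  gadd(gr, "fusion.ln_f_b", lf$db)
  dV2 <- lf$dX
  gadd(gr, "fusion.W2", crossprod(cache$Rl, dV2))
  gadd(gr, "fusion.b2", colSums(dV2))
  dZ1 <- (dV2 %*% t(pp$W2)) * (cache$Z1 > 0)
  gadd(gr, "fusion.W1", crossprod(cache$ca$Y, dZ1))
  gadd(gr, "fusion.b1", colSums(dZ1))
  dY <- dV2 + dZ1 %*% t(pp$W1)
  la <- ln_bwd(dY, cache$ca, pp$ln_a_g)
  gadd(gr, "fusion.ln_a_g", la$dg)
  gadd(gr, "fusion.ln_a_b", la$db)
  dU <- la$dX
  dU + self_mha_bwd(dU, cache$att, pp, h, B, n, gr, "fusion", lora, "fusion")
}

# ---- sequence layout for a presence pattern --------------------------------

# present: named logical (structured, text, image); n_text, n_img: token
# counts when present. Returns tags, slice indices in assembled order, the
# fusion mask and positional encodings.
seq_layout <- function(config, present, n_text, n_img) {
  lens <- c(structured = if (present[["structured"]]) 1L else 0L,
            text = if (present[["text"]]) n_text else 0L,
            image = if (present[["image"]]) n_img else 0L)
  n_tot <- sum(lens)
  if (n_tot == 0L) stop("empty-case error: all modalities absent")
  tags <- rep(names(lens), lens)
  slices <- split(seq_len(n_tot), factor(tags, levels = names(lens)[lens > 0L]))
  fusion_mask <- build_allowed_mask(config$policy, tags, tags)
  list(lens = lens[lens > 0L], n_tot = n_tot, tags = tags, slices = slices,
       fusion_mask = fusion_mask,
       pe = positional_encoding(n_tot, config$att$d_model))
}

# Assembled-row gather indices for modality m: for each sample block of
# n_tot rows, the rows belonging to slice `sl`.
gather_idx <- function(sl, n_tot, B) {
  as.vector(outer(sl, (seq_len(B) - 1L) * n_tot, `+`))
}

# ---- full forward pass on one tensorized batch -----------------------------

model_forward <- function(model, batch, layout, keep_cache = FALSE) {
  cfg <- model$config; p <- model$params
  d <- cfg$att$d_model; h <- cfg$att$n_heads; eps <- cfg$att$ln_epsilon
  B <- batch$B
  sw <- cfg$switches
  mods <- names(layout$slices)
  cache <- list(mods = mods, B = B)

  # embeddings + positional encodings (assembled positions)
  X <- list()
  if ("structured" %in% mods) {
    X$structured <- add_bias(batch$Xs %*% p[["emb.W_str"]], p[["emb.b_str"]]) +
      layout$pe[rep(layout$slices$structured, B), , drop = FALSE]
  }
  if ("text" %in% mods) {
    tokvec <- as.vector(t(batch$tok)) + 1L
    X$text <- p[["emb.E_tok"]][tokvec, , drop = FALSE] +
      layout$pe[rep(layout$slices$text, B), , drop = FALSE]
    cache$tokvec <- tokvec
  }
  if ("image" %in% mods) {
    X$image <- add_bias(batch$patches %*% p[["emb.W_img"]], p[["emb.b_img"]]) +
      layout$pe[rep(layout$slices$image, B), , drop = FALSE]
  }

  # per-modality causal encoder stack
  n_blocks <- config_n_blocks(cfg)
  cache$blocks <- list()
  for (m in mods) {
    n_m <- length(layout$slices[[m]])
    mask <- if (sw$causal_mask) build_causal_mask(n_m) else matrix(0, n_m, n_m)
    for (k in seq_len(n_blocks)) {
      pref <- sprintf("causal.%d", k)
      bl <- causal_block_fwd(X[[m]], block_params(p, pref), h, mask, B, n_m,
                             eps, lora_block(p, pref))
      X[[m]] <- bl$out
      if (keep_cache) cache$blocks[[m]][[k]] <- bl$cache
    }
  }
  cache$causal_out <- X

  # pre-fusion per-modality mean pools (contrastive views)
  pools <- lapply(mods, function(m) {
    n_m <- length(layout$slices[[m]])
    rowsum(X[[m]], rep(seq_len(B), each = n_m)) / n_m
  })
  names(pools) <- mods

  # fusion
  if (sw$pcma) {
    Z0 <- matrix(0, B * layout$n_tot, d)
    for (m in mods)
      Z0[gather_idx(layout$slices[[m]], layout$n_tot, B), ] <- X[[m]]
    fb <- fusion_block_fwd(Z0, block_params(p, "fusion"), h,
                           layout$fusion_mask, B, layout$n_tot, eps,
                           lora_block(p, "fusion"))
    pooled <- rowsum(fb$out, rep(seq_len(B), each = layout$n_tot)) / layout$n_tot
    if (keep_cache) { cache$fusion <- fb$cache; cache$Z0 <- Z0 }
  } else {
    pooled <- Reduce(`+`, lapply(mods, function(m)
      length(layout$slices[[m]]) * pools[[m]])) / layout$n_tot
  }
  cache$pooled <- pooled
  cache$pools <- pools

  list(logits = add_bias(pooled %*% p[["head.W_cls"]], p[["head.b_cls"]]),
       sev_logits = add_bias(pooled %*% p[["head.W_sev"]], p[["head.b_sev"]]),
       pools = pools, pooled = pooled, cache = if (keep_cache) cache else NULL)
}

# ---- loss + gradients on one batch -----------------------------------------

# InfoNCE forward + backward over a list of B x d modality pools.
infonce_grad <- function(pools, tau) {
  M <- length(pools); B <- nrow(pools[[1]])
  nrm <- lapply(pools, function(P) pmax(sqrt(rowSums(P * P)), 1e-12))
  U <- Map(function(P, nv) P / nv, pools, nrm)
  ndir <- M * (M - 1)
  loss <- 0
  dU <- lapply(pools, function(P) matrix(0, B, ncol(P)))
  I <- diag(B)
  for (a in seq_len(M)) for (b in seq_len(M)) {
    if (a >= b) next
    C <- (U[[a]] %*% t(U[[b]])) / tau
    Pr1 <- softmax_rows(C)
    loss <- loss - mean(log(pmax(diag(Pr1), 1e-300)))
    dC1 <- (Pr1 - I) / (B * ndir)
    dU[[a]] <- dU[[a]] + dC1 %*% U[[b]] / tau
    dU[[b]] <- dU[[b]] + crossprod(dC1, U[[a]]) / tau
    Pr2 <- softmax_rows(t(C))
    loss <- loss - mean(log(pmax(diag(Pr2), 1e-300)))
    dC2 <- (Pr2 - I) / (B * ndir)
    dU[[b]] <- dU[[b]] + dC2 %*% U[[a]] / tau
    dU[[a]] <- dU[[a]] + crossprod(dC2, U[[b]]) / tau
  }
  dP <- Map(function(du, u, nv) (du - u * rowSums(du * u)) / nv, dU, U, nrm)
  list(loss = loss / ndir, dpools = dP)
}

model_loss_grad <- function(model, batch, layout) {
  cfg <- model$config; p <- model$params
  h <- cfg$att$n_heads; eps <- cfg$att$ln_epsilon
  B <- batch$B; sw <- cfg$switches; lam <- cfg$lambdas
  fw <- model_forward(model, batch, layout, keep_cache = TRUE)
  cache <- fw$cache; mods <- cache$mods
  gr <- new.env(parent = emptyenv())

  # primary coding loss
  if (cfg$multilabel) {
    Pm <- 1 / (1 + exp(-fw$logits))
    Yb <- batch$Y
    L_code <- -mean(Yb * log(pmax(Pm, 1e-300)) +
                    (1 - Yb) * log(pmax(1 - Pm, 1e-300)))
    dlogits <- (Pm - Yb) / length(Yb)
  } else {
    Pm <- softmax_rows(fw$logits)
    L_code <- -mean(log(pmax(Pm[cbind(seq_len(B), batch$cls)], 1e-300)))
    dlogits <- Pm
    dlogits[cbind(seq_len(B), batch$cls)] <-
      dlogits[cbind(seq_len(B), batch$cls)] - 1
    dlogits <- dlogits / B
  }
  dlogits <- lam[["coding"]] * dlogits

  # auxiliary severity loss
  use_sev <- sw$mtl && lam[["severity"]] > 0
  if (use_sev) {
    Ps <- softmax_rows(fw$sev_logits)
    L_sev <- -mean(log(pmax(Ps[cbind(seq_len(B), batch$sev + 1L)], 1e-300)))
    dsev <- Ps
    dsev[cbind(seq_len(B), batch$sev + 1L)] <-
      dsev[cbind(seq_len(B), batch$sev + 1L)] - 1
    dsev <- lam[["severity"]] * dsev / B
  } else {
    L_sev <- NA_real_
    dsev <- matrix(0, B, 3L)
  }

  # auxiliary contrastive loss over pre-fusion pools
  use_con <- sw$mtl && lam[["contrastive"]] > 0 && length(mods) >= 2L && B >= 2L
  if (use_con) {
    nce <- infonce_grad(cache$pools, cfg$tau)
    L_con <- nce$loss
  } else L_con <- NA_real_

  total <- lam[["coding"]] * L_code +
    (if (use_con) lam[["contrastive"]] * L_con else 0) +
    (if (use_sev) lam[["severity"]] * L_sev else 0)

  # ---- backward ----
  gadd(gr, "head.W_cls", crossprod(cache$pooled, dlogits))
  gadd(gr, "head.b_cls", colSums(dlogits))
  dpooled <- dlogits %*% t(p[["head.W_cls"]])
  if (use_sev) {
    gadd(gr, "head.W_sev", crossprod(cache$pooled, dsev))
    gadd(gr, "head.b_sev", colSums(dsev))
    dpooled <- dpooled + dsev %*% t(p[["head.W_sev"]])
  }

  dX <- list()  # gradients w.r.t. causal-stage outputs, per modality
  if (sw$pcma) {
    dZ <- dpooled[rep(seq_len(B), each = layout$n_tot), , drop = FALSE] /
      layout$n_tot
    dZ0 <- fusion_block_bwd(dZ, cache$fusion, block_params(p, "fusion"), h,
                            B, layout$n_tot, gr, lora_block(p, "fusion"))
    for (m in mods)
      dX[[m]] <- dZ0[gather_idx(layout$slices[[m]], layout$n_tot, B), ,
                     drop = FALSE]
  } else {
    for (m in mods) {
      n_m <- length(layout$slices[[m]])
      dX[[m]] <- dpooled[rep(seq_len(B), each = n_m), , drop = FALSE] /
        layout$n_tot
    }
  }
  if (use_con) {
    for (mi in seq_along(mods)) {
      m <- mods[mi]; n_m <- length(layout$slices[[m]])
      dX[[m]] <- dX[[m]] +
        lam[["contrastive"]] *
        nce$dpools[[mi]][rep(seq_len(B), each = n_m), , drop = FALSE] / n_m
    }
  }

  n_blocks <- config_n_blocks(cfg)
  for (m in mods) {
    n_m <- length(layout$slices[[m]])
    mask <- if (sw$causal_mask) build_causal_mask(n_m) else matrix(0, n_m, n_m)
    for (k in rev(seq_len(n_blocks))) {
      pref <- sprintf("causal.%d", k)
      dX[[m]] <- causal_block_bwd(dX[[m]], cache$blocks[[m]][[k]],
                                  block_params(p, pref), h, mask, B, n_m, gr,
                                  pref, lora_block(p, pref), pref)
    }
  }

  # embedding gradients
  if ("structured" %in% mods) {
    gadd(gr, "emb.W_str", crossprod(batch$Xs, dX$structured))
    gadd(gr, "emb.b_str", colSums(dX$structured))
  }
  if ("text" %in% mods) {
    gtok <- rowsum(dX$text, cache$tokvec)
    gE <- matrix(0, nrow(p[["emb.E_tok"]]), ncol(p[["emb.E_tok"]]))
    gE[as.integer(rownames(gtok)), ] <- gtok
    gadd(gr, "emb.E_tok", gE)
  }
  if ("image" %in% mods) {
    gadd(gr, "emb.W_img", crossprod(batch$patches, dX$image))
    gadd(gr, "emb.b_img", colSums(dX$image))
  }

  list(total = total, losses = c(coding = L_code, contrastive = L_con,
                                 severity = L_sev),
       grads = as.list(gr), logits = fw$logits)
}

#' Encode an assembled sequence through the causal encoder stack
#'
#' Runs the per-modality causal blocks of a model on an already embedded and
#' positioned \code{\link{feature_sequence}} (as produced by
#' \code{\link{assemble_sequence}}). Exposes the causal-stage internal
#' representations, e.g. for causality checks.
#'
#' @param model an \code{mm_model}.
#' @param fs a \code{feature_sequence} with d_model columns.
#' @return a \code{feature_sequence} of identical shape.
#' @export
causal_encode <- function(model, fs) {
  cfg <- model$config; p <- model$params
  h <- cfg$att$n_heads; eps <- cfg$att$ln_epsilon
  vals <- fs$values
  for (m in unique(fs$tags)) {
    idx <- which(fs$tags == m)
    Xm <- vals[idx, , drop = FALSE]
    n_m <- length(idx)
    mask <- if (cfg$switches$causal_mask) build_causal_mask(n_m)
            else matrix(0, n_m, n_m)
    for (k in seq_len(config_n_blocks(cfg))) {
      pref <- sprintf("causal.%d", k)
      Xm <- causal_block_fwd(Xm, block_params(p, pref), h, mask, 1L, n_m,
                             eps, lora_block(p, pref))$out
    }
    vals[idx, ] <- Xm
  }
  feature_sequence(vals, fs$tags, fs$positions)
}
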