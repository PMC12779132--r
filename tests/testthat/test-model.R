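test_that("forward pass honors the shape contract for every switch setting", {
  ds <- tiny_dataset(n = 8)
  for (sw in list(c(TRUE, TRUE, TRUE), c(FALSE, FALSE, FALSE),
                  c(FALSE, TRUE, TRUE), c(TRUE, FALSE, TRUE))) {
    cfg <- tiny_model_config(causal_mask = sw[1], pcma = sw[2], mtl = sw[3])
    model <- build_model(cfg, 2, 3, seed = 3)
    tens <- mmcoder:::dataset_tensors(model, ds, 1:2)
    fw <- mmcoder:::model_forward(model, tens[[1]], tens[[1]]$layout)
    expect_equal(dim(fw$logits), c(2, 2))
    expect_equal(dim(fw$sev_logits), c(2, 3))
    expect_equal(names(fw$pools), c("structured", "text", "image"))
    expect_true(all(vapply(fw$pools, function(p) all(dim(p) == c(2, 8)), TRUE)))
    expect_true(all(is.finite(fw$logits)))
  }
})

test_that("enabling the fusion stage strictly increases the parameter count", {
  on <- build_model(tiny_model_config(pcma = TRUE), 2, 3, seed = 1)
  off <- build_model(tiny_model_config(pcma = FALSE), 2, 3, seed = 1)
  expect_gt(count_parameters(on), count_parameters(off))
})

test_that("analytic gradients match finite differences across parameter types", {
  ds <- tiny_dataset(n = 6)
  model <- build_model(tiny_model_config(), 2, 3, seed = 7)
  tens <- mmcoder:::dataset_tensors(model, ds, 1:6)
  g <- tens[[1]]
  lg <- mmcoder:::model_loss_grad(model, g, g$layout)
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    mmcoder:::model_loss_grad(m2, g, g$layout)$total
  }
  eps <- 1e-6
  set.seed(12)
  for (nm in names(model$params)) {
    grad <- lg$grads[[nm]]
    expect_false(is.null(grad), info = nm)
    for (i in sample(length(model$params[[nm]]),
                     min(2, length(model$params[[nm]])))) {
      pp <- model$params
      pp[[nm]][i] <- pp[[nm]][i] + eps; up <- loss_at(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * eps; dn <- loss_at(pp)
      num <- (up - dn) / (2 * eps)
      expect_equal(grad[i], num, tolerance = 1e-4,
                   info = sprintf("%s[%d]", nm, i))
    }
  }
})

test_that("early stopping fires after exactly patience non-improving epochs", {
  ds <- tiny_dataset(n = 16)
  model <- build_model(tiny_model_config(), 2, 3, seed = 4)
  # a vanishing learning rate freezes the validation metric
  fit <- train_model(model, ds, train_config(epochs = 20, batch_size = 8,
                                             lr = 1e-12, patience = 2,
                                             seed = 1))
  expect_equal(nrow(fit$history), 3)
  expect_equal(fit$stop_reason, "early_stop")
  expect_equal(fit$best_epoch, 1)
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset(n = 24)
  run <- function() {
    model <- build_model(tiny_model_config(), 2, 3, seed = 9)
    train_model(model, ds, train_config(epochs = 3, batch_size = 8, seed = 5))
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("the degenerate all-off model still trains and evaluates", {
  ds <- tiny_dataset(n = 24)
  model <- build_model(tiny_model_config(causal_mask = FALSE, pcma = FALSE,
                                         mtl = FALSE), 2, 3, seed = 2)
  fit <- train_model(model, ds, train_config(epochs = 2, batch_size = 8,
                                             seed = 3))
  rep <- evaluate_model(fit$model, ds, "test")
  expect_true(all(unlist(rep[c("subset_accuracy", "macro_f1", "jaccard",
                               "hamming_loss")]) >= 0))
})

test_that("records with a missing modality flow through training", {
  ds <- tiny_dataset(n = 24)
  for (i in seq(1, 24, by = 3)) ds$records[[i]]$image <- NULL
  model <- build_model(tiny_model_config(), 2, 3, seed = 2)
  fit <- train_model(model, ds, train_config(epochs = 2, batch_size = 8,
                                             seed = 3))
  pr <- predict_model(fit$model, ds)
  expect_true(all(is.finite(pr$scores)))
  expect_equal(rowSums(pr$Yhat), rep(1, 24))
})

test_that("truncating the assembled sequence preserves earlier causal encodings", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, 2, 3, seed = 8)
  ecfg <- embedding_config(d_model = 8, patch_size = 2, vocab_size = 8)
  ep <- list(W_img = model$params[["emb.W_img"]],
             b_img = model$params[["emb.b_img"]],
             E_tok = model$params[["emb.E_tok"]],
             W_str = model$params[["emb.W_str"]],
             b_str = model$params[["emb.b_str"]])
  rec <- tiny_dataset(n = 2)$records[[1]]
  fs <- assemble_sequence(list(embed_structured(rec$structured, ep),
                               embed_text(rec$text, ecfg, ep),
                               embed_image(rec$image, ecfg, ep)), ecfg)
  full <- causal_encode(model, fs)
  n <- nrow(fs$values)
  for (cut in c(3, 5, n - 1)) {
    fs_cut <- feature_sequence(fs$values[1:cut, , drop = FALSE],
                               fs$tags[1:cut], fs$positions[1:cut])
    part <- causal_encode(model, fs_cut)
    expect_lt(max(abs(part$values - full$values[1:cut, , drop = FALSE])),
              1e-10)
  }
})
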