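test_that("adapter forward matches hand computation and zero-update contract", {
  # B = 0: exactly the base map (also the initialization state)
  set.seed(2)
  W0 <- matrix(rnorm(12), 3, 4)
  ad <- lora_adapter(W0, rank = 2)
  x <- rnorm(4)
  expect_identical(lora_forward(ad, x), drop(W0 %*% x))

  # worked rank-1 example: h = x + (x2, 0)
  ad1 <- lora_adapter(diag(2), rank = 1, A_lr = matrix(c(0, 1), 1),
                      B_lr = matrix(c(1, 0), 2))
  expect_equal(lora_forward(ad1, c(3, 5)), c(8, 5))
  expect_equal(merge_adapter(ad1), rbind(c(1, 1), c(0, 1)))

  # row-matrix input orientation
  X <- matrix(rnorm(8), 2, 4)
  expect_equal(lora_forward(ad, X), X %*% t(W0))

  expect_equal(lora_param_count(ad), 2 * (4 + 3))
  expect_error(lora_forward(ad, rnorm(5)), "shape error")
  expect_error(lora_adapter(W0, rank = 4), "rank")
})

test_that("merged weights are forward-equivalent across random adapters", {
  set.seed(44)
  worst <- 0
  for (i in 1:50) {
    d_in <- sample(3:10, 1); d_out <- sample(3:10, 1)
    r <- sample(seq_len(min(d_in, d_out) - 1L), 1)
    ad <- lora_adapter(matrix(rnorm(d_out * d_in), d_out), r,
                       A_lr = matrix(rnorm(r * d_in), r),
                       B_lr = matrix(rnorm(d_out * r), d_out))
    Wm <- merge_adapter(ad)
    for (k in 1:4) {
      x <- rnorm(d_in)
      a <- lora_forward(ad, x); b <- drop(Wm %*% x)
      worst <- max(worst, max(abs(a - b) / pmax(abs(b), 1)))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("rank saturation: a full-rank adapter fits any target update", {
  set.seed(8)
  d_in <- 6; d_out <- 4; r <- min(d_in, d_out)
  target <- matrix(rnorm(d_out * d_in), d_out)
  s <- svd(target)                       # least-squares optimum at full rank
  A <- t(s$v); B <- s$u %*% diag(s$d)
  expect_lt(max(abs(B %*% A - target)), 1e-10)
  ad <- lora_adapter(matrix(0, d_out, d_in), r, A_lr = A, B_lr = B)
  expect_equal(merge_adapter(ad), target, tolerance = 1e-10)
})

test_that("adapter archives round-trip through the manifest format", {
  set.seed(3)
  ads <- list("causal.1.q" = lora_adapter(matrix(rnorm(24), 4), 2,
                                          B_lr = matrix(rnorm(8), 4)),
              "fusion.v" = lora_adapter(matrix(rnorm(36), 6), 3))
  dir <- withr::local_tempdir()
  save_adapters(ads, dir)
  back <- load_adapters(dir)
  expect_equal(names(back), names(ads))
  for (nm in names(ads)) {
    expect_equal(back[[nm]]$W0, ads[[nm]]$W0, tolerance = 1e-12)
    expect_equal(back[[nm]]$B_lr, ads[[nm]]$B_lr, tolerance = 1e-12)
    expect_equal(back[[nm]]$A_lr, ads[[nm]]$A_lr, tolerance = 1e-12)
    expect_equal(back[[nm]]$rank, ads[[nm]]$rank)
  }
})

test_that("adapted model equals base model at initialization (B = 0)", {
  ds <- tiny_dataset()
  base <- build_model(tiny_model_config(), 2, 3, seed = 6)
  adapted <- build_model(tiny_model_config(lora_enabled = TRUE, lora_rank = 2),
                         2, 3, seed = 6)
  pr_b <- predict_model(base, ds)
  pr_a <- predict_model(adapted, ds)
  expect_identical(pr_b$scores, pr_a$scores)
})

test_that("training an adapted model leaves base q/v weights bit-identical", {
  ds <- tiny_dataset(n = 24)
  model <- build_model(tiny_model_config(lora_enabled = TRUE, lora_rank = 2),
                       2, 3, seed = 6)
  before <- model$params
  fit <- train_model(model, ds, train_config(epochs = 3, batch_size = 8,
                                             seed = 2))
  after <- fit$model$params
  frozen <- mmcoder:::frozen_names(model)
  expect_true(length(frozen) >= 4)
  for (nm in frozen) expect_identical(after[[nm]], before[[nm]])
  # adapters did move
  moved <- vapply(grep("^lora\\..*\\.B$", names(after), value = TRUE),
                  function(nm) max(abs(after[[nm]] - before[[nm]])), 0)
  expect_gt(max(moved), 0)
  # trainable count excludes exactly the frozen entries
  expect_equal(count_parameters(fit$model) - count_parameters(fit$model, TRUE),
               sum(vapply(before[frozen], length, 0L)))
})
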