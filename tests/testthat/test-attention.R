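test_that("masked attention handles singleton, causal row 0 and uniform cases", {
  # a single visible token returns its value row unchanged
  out <- masked_attention(matrix(rnorm(4), 1), matrix(rnorm(4), 1),
                          matrix(c(2, 3), 1), matrix(0, 1, 1))
  expect_equal(out, matrix(c(2, 3), 1))

  # under the causal mask, row 0 sees only V row 0
  set.seed(1)
  n <- 6
  Q <- matrix(rnorm(n * 4), n); K <- matrix(rnorm(n * 4), n)
  V <- matrix(rnorm(n * 3), n)
  out <- masked_attention(Q, K, V, build_causal_mask(n))
  expect_equal(out[1, ], V[1, ])

  # all-equal visible scores average uniformly
  out <- masked_attention(matrix(0, 2, 4), matrix(rnorm(8), 2),
                          rbind(c(1, 0), c(0, 1)), matrix(0, 2, 2))
  expect_equal(out, rbind(c(0.5, 0.5), c(0.5, 0.5)))
})

test_that("attention weights are row-stochastic with exact zeros on masked pairs", {
  set.seed(7)
  for (n in c(2, 5, 11)) {
    Q <- matrix(rnorm(n * 8), n); K <- matrix(rnorm(n * 8), n)
    V <- matrix(rnorm(n * 8), n)
    res <- masked_attention(Q, K, V, build_causal_mask(n),
                            return_weights = TRUE)
    expect_equal(rowSums(res$weights), rep(1, n))
    expect_true(all(res$weights[upper.tri(res$weights)] == 0))
    expect_true(all(res$weights >= 0))
  }
})

test_that("zero mask reproduces unmasked attention and the scale identity holds", {
  set.seed(3)
  n <- 7; Q <- matrix(rnorm(n * 8), n); K <- matrix(rnorm(n * 8), n)
  V <- matrix(rnorm(n * 5), n)
  plain <- {
    S <- Q %*% t(K) / sqrt(8)
    E <- exp(S - apply(S, 1, max))
    (E / rowSums(E)) %*% V
  }
  expect_equal(masked_attention(Q, K, V, matrix(0, n, n)), plain,
               tolerance = 1e-12)
  # multiplying Q by c and K by 1/c leaves the logits (hence output) unchanged
  expect_equal(masked_attention(3 * Q, K / 3, V, matrix(0, n, n)), plain,
               tolerance = 1e-9)
})

test_that("degenerate masks and shape mismatches are rejected", {
  Q <- matrix(rnorm(8), 2); K <- Q; V <- matrix(rnorm(4), 2)
  expect_error(masked_attention(Q, K, V, matrix(-Inf, 2, 2)), "degenerate-mask")
  expect_error(masked_attention(Q, matrix(rnorm(6), 2, 3), V), "shape")
  expect_error(masked_attention(Q, K, V, matrix(1, 2, 2)), "0 or -Inf")
})

test_that("causal block respects the causality contract for n up to 16", {
  cfg <- attention_config(d_model = 8, n_heads = 2, ffn_hidden = 12)
  set.seed(11)
  params <- init_attention_block(cfg)
  for (n in c(2, 4, 9, 16)) {
    X <- random_sequence(n, 8, seed = n)
    out <- multi_head_causal_block(X, cfg, params)
    expect_equal(dim(out$values), dim(X$values))
    for (j in seq(2, n)) {        # perturb token j, check positions < j
      Xp <- X
      Xp$values[j, ] <- Xp$values[j, ] + 10
      outp <- multi_head_causal_block(Xp, cfg, params)
      expect_lt(max(abs(outp$values[seq_len(j - 1), , drop = FALSE] -
                        out$values[seq_len(j - 1), , drop = FALSE])), 1e-6)
    }
  }
  # n = 1 stays finite
  out1 <- multi_head_causal_block(random_sequence(1, 8, seed = 2), cfg, params)
  expect_true(all(is.finite(out1$values)))
})

test_that("an all-zero mask makes the causal block match a standard block", {
  cfg <- attention_config(d_model = 8, n_heads = 2, ffn_hidden = 12)
  set.seed(21)
  params <- init_attention_block(cfg)
  X <- random_sequence(6, 8, seed = 8)
  got <- multi_head_causal_block(X, cfg, params, mask = matrix(0, 6, 6))
  want <- reference_standard_block(X$values, cfg, params)
  expect_equal(got$values, want, tolerance = 1e-10)
})

test_that("causal block rejects a width mismatch", {
  cfg <- attention_config(d_model = 8, n_heads = 2)
  set.seed(1)
  params <- init_attention_block(cfg)
  expect_error(multi_head_causal_block(random_sequence(3, 6), cfg, params),
               "config error")
})
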