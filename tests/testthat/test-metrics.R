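test_that("the five metrics match their worked examples", {
  Y <- rbind(c(1, 1), c(0, 1))
  expect_equal(subset_accuracy(Y, Y), 1.0)
  expect_equal(subset_accuracy(Y, rbind(c(1, 1), c(1, 1))), 0.5)

  expect_equal(hamming_loss(Y, Y), 0.0)
  Y3 <- rbind(c(1, 0, 1), c(0, 1, 0))
  Y3f <- Y3; Y3f[1, 2] <- 1
  expect_equal(hamming_loss(Y3, Y3f), 1 / 6)
  expect_equal(hamming_loss(Y3, 1 - Y3), 1.0)

  # class 1: TP=1 FP=1 FN=0; class 2: TP=1 FP=0 FN=1 -> macro F1 = 2/3
  Yt <- rbind(c(1, 1), c(0, 1)); Yp <- rbind(c(1, 0), c(1, 1))
  expect_equal(macro_f1(Yt, Yp), 2 / 3)
  br <- macro_f1(Yt, Yp, breakdown = TRUE)
  expect_equal(br$per_class$precision, c(0.5, 1))
  expect_equal(br$per_class$recall, c(1, 0.5))
  # class never predicted and never true contributes 0
  expect_equal(macro_f1(cbind(Yt, 0), cbind(Yp, 0)), (2 / 3 + 2 / 3 + 0) / 3)

  # AUC: separable, reversed, and all-tied columns
  Yc <- cbind(c(1, 1, 0, 0))
  expect_equal(macro_auc(Yc, cbind(c(4, 3, 2, 1))), 1.0)
  expect_equal(macro_auc(Yc, cbind(c(1, 2, 3, 4))), 0.0)
  expect_equal(macro_auc(Yc, cbind(rep(7, 4))), 0.5)
  expect_error(macro_auc(cbind(c(1, 1)), cbind(c(1, 2))), "undefined-AUC")

  # sample-averaged Jaccard
  expect_equal(jaccard_index(Y, Y), 1.0)
  expect_equal(jaccard_index(rbind(c(1, 1, 0)), rbind(c(1, 0, 1))), 1 / 3)
  expect_equal(jaccard_index(rbind(c(1, 0)), rbind(c(0, 1))), 0.0)
  expect_equal(jaccard_index(rbind(c(0, 0)), rbind(c(0, 0))), 1.0)
})

test_that("comparison arithmetic rounds half-up at one decimal", {
  expect_equal(relative_change(49.0, 55.2), 12.7)
  expect_equal(relative_change(0.046, 0.034), 26.1)
  expect_equal(relative_change(3, 3), 0.0)
  expect_equal(relative_change(100, 100.25), 0.3)   # half rounds up
  expect_error(relative_change(0, 5), "zero reference")

  expect_equal(absolute_drop(64.8, 63.2), 1.6)
  expect_equal(absolute_drop(65.5, 64.1), 1.4)
  expect_equal(absolute_drop(5, 5), 0.0)
})

test_that("metric invariants hold on random instances", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(1:6, 1); L <- sample(1:5, 1)
    Y <- matrix(rbinom(N * L, 1, 0.4), N, L)
    Yh <- matrix(rbinom(N * L, 1, 0.5), N, L)
    sa <- subset_accuracy(Y, Yh); hl <- hamming_loss(Y, Yh)
    expect_identical(sa == 1, hl == 0)
    expect_gte(sa, 1 - L * hl - 1e-12)
    # column permutation invariance
    perm <- sample(L)
    expect_equal(macro_f1(Y[, perm, drop = FALSE], Yh[, perm, drop = FALSE]),
                 macro_f1(Y, Yh))
    expect_equal(jaccard_index(Y, Yh),
                 jaccard_index(Y[, perm, drop = FALSE],
                               Yh[, perm, drop = FALSE]))
    # AUC invariance under strictly monotone score transforms
    S <- matrix(rnorm(N * L), N, L)
    ok <- tryCatch({ macro_auc(Y, S); TRUE }, error = function(e) FALSE)
    if (ok)
      expect_equal(macro_auc(Y, S), macro_auc(Y, exp(2 * S) + 1),
                   tolerance = 1e-12)
  }
})

test_that("metrics agree with the pROC package on random score matrices", {
  skip_if_not_installed("pROC")
  set.seed(55)
  for (i in 1:20) {
    N <- sample(8:30, 1); L <- sample(2:4, 1)
    Y <- matrix(rbinom(N * L, 1, 0.5), N, L)
    S <- matrix(rnorm(N * L), N, L)
    ref <- c()
    for (j in seq_len(L)) {
      if (length(unique(Y[, j])) < 2) next
      ref <- c(ref, as.numeric(suppressMessages(
        pROC::auc(pROC::roc(Y[, j], S[, j], direction = "<", quiet = TRUE)))))
    }
    if (length(ref) == 0) next
    expect_equal(macro_auc(Y, S), mean(ref), tolerance = 1e-9)
  }
})

test_that("evaluate_all aggregates consistently and reports percent scale", {
  set.seed(77)
  N <- 40; L <- 3
  Y <- matrix(rbinom(N * L, 1, 0.4), N, L)
  S <- matrix(rnorm(N * L), N, L)
  Yh <- (S > 0) * 1L
  rep <- evaluate_all(Y, S, Yh)
  expect_equal(rep$subset_accuracy, subset_accuracy(Y, Yh))
  expect_equal(rep$macro_f1, macro_f1(Y, Yh))
  expect_equal(rep$macro_auc, macro_auc(Y, S))
  expect_equal(rep$jaccard, jaccard_index(Y, Yh))
  expect_equal(rep$hamming_loss, hamming_loss(Y, Yh))
  vals <- unlist(rep[c("subset_accuracy", "macro_f1", "macro_auc", "jaccard",
                       "hamming_loss")])
  expect_true(all(vals >= 0 & vals <= 1))
  expect_equal(unname(rep$percent[["Hamming Loss(%)"]]),
               unname(mmcoder:::round_half_up(100 * rep$hamming_loss)))
  expect_named(rep$percent, c("Subset Accuracy(%)", "Macro F1(%)",
                              "Macro AUC-ROC", "Jaccard Index(%)",
                              "Hamming Loss(%)"))
})
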