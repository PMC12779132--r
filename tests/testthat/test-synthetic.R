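small_gen <- function(...) {
  generator_config(n_samples = 60, image_size = 8, text_length = 6,
                   vocab_size = 12, structured_dim = 4, seed = 9, ...)
}

test_that("generation is seed-reproducible and class-balanced", {
  d1 <- generate_dataset(small_gen())
  d2 <- generate_dataset(small_gen())
  expect_identical(d1, d2)
  cls <- vapply(d1$records, function(r) which.max(r$labels), 0L)
  tab <- table(cls)
  expect_true(all(abs(tab - 20) <= 0.2 * 20))
  # splits disjoint, cover everything
  sp <- d1$splits
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:60)
  expect_equal(length(intersect(sp$train, sp$val)), 0)
  # record invariants
  for (r in d1$records[1:5]) {
    expect_true(all(r$image >= 0 & r$image <= 1))
    expect_true(all(r$text >= 0 & r$text < 12))
    expect_equal(sum(r$labels), 1)
  }
  # severity terciles roughly balanced
  sev <- table(vapply(d1$records, `[[`, "", "severity"))
  expect_true(all(sev >= 10))
})

test_that("per-class structured means concentrate around the true means", {
  cfg <- generator_config(seed = 1)          # n = 600, C = 3, delta = 4
  ds <- generate_dataset(cfg)
  X <- do.call(rbind, lapply(ds$records, `[[`, "structured"))
  cls <- ds$params$classes
  for (c in 1:3) {
    mhat <- colMeans(X[cls == c, , drop = FALSE])
    expect_lt(max(abs(mhat - ds$params$class_means[c, ])), 3 / sqrt(200))
  }
  # pairwise mean distances equal the configured separation
  mu <- ds$params$class_means
  for (a in 1:2) for (b in (a + 1):3)
    expect_equal(sqrt(sum((mu[a, ] - mu[b, ])^2)), 4)
})

test_that("reference-classifier accuracy is monotone in class separation", {
  accs <- vapply(c(0.5, 2, 4), function(delta) {
    centroid_accuracy(generate_dataset(generator_config(
      n_samples = 300, class_separation = delta, seed = 33)))
  }, 0)
  expect_gte(accs[2], accs[1] - 0.02)
  expect_gte(accs[3], accs[2] - 0.02)
  expect_gt(accs[3], 0.85)       # delta = 4 is nearly separable
  expect_lt(accs[1], 0.75)       # delta = 0.5 is close to chance
})

test_that("input noise corrupts exactly the contracted number of entries", {
  ds <- generate_dataset(small_gen())
  expect_identical(apply_input_noise(ds, 0), ds)
  nz <- apply_input_noise(ds, 0.2, seed = 4)
  total <- sum(vapply(ds$records, function(r)
    length(r$structured) + length(r$image), 0))
  diffs <- sum(vapply(seq_along(ds$records), function(i) {
    sum(ds$records[[i]]$structured != nz$records[[i]]$structured) +
      sum(ds$records[[i]]$image != nz$records[[i]]$image)
  }, 0))
  expect_equal(diffs, floor(0.2 * total))
  # labels, severity, count untouched; images still valid
  expect_equal(length(nz$records), length(ds$records))
  for (i in seq_along(ds$records)) {
    expect_identical(nz$records[[i]]$labels, ds$records[[i]]$labels)
    expect_identical(nz$records[[i]]$severity, ds$records[[i]]$severity)
    expect_true(all(nz$records[[i]]$image >= 0 & nz$records[[i]]$image <= 1))
  }
  # same seed, same corruption
  expect_identical(nz, apply_input_noise(ds, 0.2, seed = 4))
  expect_error(apply_input_noise(ds, 1.5), "fraction")
})

test_that("training subsampling drops only training indices", {
  ds <- generate_dataset(small_gen())
  expect_identical(subsample_training(ds, 1.0), ds)
  sub <- subsample_training(ds, 0.7, seed = 2)
  expect_equal(length(sub$splits$train), floor(0.7 * length(ds$splits$train)))
  expect_true(all(sub$splits$train %in% ds$splits$train))
  expect_identical(sub$splits$val, ds$splits$val)
  expect_identical(sub$splits$test, ds$splits$test)
  expect_identical(sub$records, ds$records)
  dropped <- setdiff(ds$splits$train, sub$splits$train)
  expect_equal(length(intersect(dropped, sub$splits$train)), 0)
  expect_equal(sort(c(dropped, sub$splits$train)), ds$splits$train)
})

test_that("modality dropping strips the named modality but never the last one", {
  ds <- generate_dataset(small_gen())
  dd <- drop_modality(ds, "image", fraction = 0.3, seed = 6)
  n_missing <- sum(vapply(dd$records, function(r) is.null(r$image), TRUE))
  expect_equal(n_missing, floor(0.3 * 60))
  for (r in dd$records)
    expect_gte(length(mmcoder:::record_modalities(r)), 1)
})

test_that("fixtures round-trip exactly through JSON Lines", {
  ds <- generate_dataset(small_gen())
  dir <- withr::local_tempdir()
  write_fixtures(ds, dir)
  back <- read_fixtures(dir)
  expect_equal(length(back$records), length(ds$records))
  for (i in c(1, 17, 60)) {
    expect_identical(back$records[[i]]$case_id, ds$records[[i]]$case_id)
    expect_equal(back$records[[i]]$image, ds$records[[i]]$image)
    expect_identical(back$records[[i]]$text, ds$records[[i]]$text)
    expect_equal(back$records[[i]]$structured, ds$records[[i]]$structured)
    expect_identical(back$records[[i]]$labels, ds$records[[i]]$labels)
    expect_identical(back$records[[i]]$severity, ds$records[[i]]$severity)
  }
  expect_equal(back$splits, lapply(ds$splits, as.integer))
  expect_equal(back$params$class_means, ds$params$class_means)
  expect_equal(back$params$templates, ds$params$templates)
})
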