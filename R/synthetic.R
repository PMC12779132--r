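# Seeded generator of multimodal case records with known class structure:
# class-dependent image patterns, class-skewed token distributions and
# class-conditional Gaussian structured features, plus the input-noise and
# training-set-reduction perturbations used by the robustness harness.

#' Synthetic dataset generator configuration
#'
#' Defaults define the desk-scale study conditions: 600 cases, 3 mutually
#' exclusive classes, 16 x 16 images, vocabulary 32, 12 text tokens, 8
#' structured features, class-mean separation 4 and pixel noise 0.1.
#'
#' @param n_samples number of case records.
#' @param n_classes number of mutually exclusive classes C (>= 2).
#' @param image_size side length of the square image grid.
#' @param vocab_size text vocabulary size.
#' @param text_length tokens per text sequence.
#' @param structured_dim length d_s of the structured vector (>= n_classes).
#' @param class_separation delta: Euclidean distance between every pair of
#'   class means in structured space.
#' @param pixel_noise sigma of the Gaussian pixel noise added to the class
#'   image template (before clipping to [0, 1]).
#' @param class_token_mass probability mass a class places on its own
#'   vocabulary block (the rest is spread uniformly over the whole
#'   vocabulary).
#' @param split train/validation/test fractions (sum to 1).
#' @param seed integer seed fixing every random draw.
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(n_samples = 600L, n_classes = 3L,
                             image_size = 16L, vocab_size = 32L,
                             text_length = 12L, structured_dim = 8L,
                             class_separation = 4, pixel_noise = 0.1,
                             class_token_mass = 0.6,
                             split = c(train = 0.7, val = 0.15, test = 0.15),
                             seed = 1L) {
  if (n_classes < 2L) stop("invalid config: need at least two classes")
  if (class_separation <= 0) stop("invalid config: class_separation must be > 0")
  if (structured_dim < n_classes)
    stop("invalid config: structured_dim must be >= n_classes")
  if (any(c(n_samples, image_size, vocab_size, text_length) < 1L))
    stop("invalid config: sizes must be positive")
  if (abs(sum(split) - 1) > 1e-9) stop("invalid config: split must sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 vocab_size = as.integer(vocab_size),
                 text_length = as.integer(text_length),
                 structured_dim = as.integer(structured_dim),
                 class_separation = class_separation,
                 pixel_noise = pixel_noise,
                 class_token_mass = class_token_mass,
                 split = split, seed = as.integer(seed)),
            class = "generator_config")
}

# Class means at scaled basis vectors: ||mu_c - mu_c'|| = delta for all pairs.
class_means <- function(C, d_s, delta) {
  M <- matrix(0, C, d_s)
  M[cbind(seq_len(C), seq_len(C))] <- delta / sqrt(2)
  M
}

# Deterministic class image template on [0,1]: stripes / quadrant /
# checkerboard patterns cycled over classes.
class_template <- function(c, H, W) {
  base <- matrix(0.2, H, W)
  amp <- 0.6
  kind <- (c - 1L) %% 4L
  period <- 4L + 2L * ((c - 1L) %/% 4L)
  ri <- matrix(rep(seq_len(H), W), H, W)
  ci <- matrix(rep(seq_len(W), each = H), H, W)
  on <- switch(as.character(kind),
               "0" = ((ri - 1L) %/% (period %/% 2L)) %% 2L == 0L,       # horizontal stripes
               "1" = ((ci - 1L) %/% (period %/% 2L)) %% 2L == 0L,       # vertical stripes
               "2" = ri <= H %/% 2L & ci <= W %/% 2L,                   # bright quadrant
               "3" = (((ri - 1L) %/% 2L) + ((ci - 1L) %/% 2L)) %% 2L == 0L) # checker
  base + amp * on
}

# Class-skewed token distribution over the vocabulary.
token_probs <- function(C, vocab, mass) {
  block <- vocab %/% C
  P <- matrix((1 - mass) / vocab, C, vocab)
  for (c in seq_len(C)) {
    idx <- ((c - 1L) * block + 1L):(c * block)
    P[c, idx] <- P[c, idx] + mass / block
  }
  P
}

#' Generate a synthetic multimodal dataset
#'
#' Each record of class c carries: structured features ~ N(mu_c, I) with all
#' pairwise class-mean distances equal to \code{class_separation}; an image
#' built from the class template plus Gaussian pixel noise clipped to [0,1];
#' text tokens drawn from a class-skewed vocabulary distribution; a one-hot
#' label vector; and a severity label from tercile bins of the latent
#' structured deviation from the class mean. Splits are stratified by class.
#'
#' @param config a \code{\link{generator_config}}.
#' @return an object of class \code{synthetic_dataset}: \code{records} (list
#'   of \code{\link{case_record}}), \code{params} (true generative
#'   parameters), and \code{splits} (disjoint train/val/test index vectors).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_samples; C <- config$n_classes
  H <- config$image_size; d_s <- config$structured_dim
  mu <- class_means(C, d_s, config$class_separation)
  templates <- lapply(seq_len(C), function(c) class_template(c, H, H))
  tp <- token_probs(C, config$vocab_size, config$class_token_mass)
  classes <- sample(rep(seq_len(C), length.out = n))
  X <- matrix(stats::rnorm(n * d_s), n, d_s) + mu[classes, , drop = FALSE]
  dev <- sqrt(rowSums((X - mu[classes, , drop = FALSE])^2))
  terc <- stats::quantile(dev, c(1, 2) / 3)
  sev <- c("mild", "moderate", "severe")[1L + (dev > terc[1]) + (dev > terc[2])]
  records <- vector("list", n)
  for (i in seq_len(n)) {
    img <- templates[[classes[i]]] +
      matrix(stats::rnorm(H * H, sd = config$pixel_noise), H, H)
    img <- pmin(pmax(img, 0), 1)
    txt <- sample.int(config$vocab_size, config$text_length, replace = TRUE,
                      prob = tp[classes[i], ]) - 1L
    lab <- integer(C); lab[classes[i]] <- 1L
    records[[i]] <- case_record(sprintf("case_%04d", i), image = img,
                                text = txt, structured = X[i, ],
                                labels = lab, severity = sev[i])
  }
  # stratified shuffled split
  tr <- va <- te <- integer(0)
  for (c in seq_len(C)) {
    idx <- sample(which(classes == c))
    k <- length(idx)
    n_tr <- round(config$split[[1]] * k)
    n_va <- round(config$split[[2]] * k)
    tr <- c(tr, idx[seq_len(n_tr)])
    va <- c(va, idx[n_tr + seq_len(n_va)])
    if (n_tr + n_va < k) te <- c(te, idx[(n_tr + n_va + 1L):k])
  }
  structure(list(records = records,
                 params = list(config = config, class_means = mu,
                               templates = templates, token_probs = tp,
                               classes = classes),
                 splits = list(train = sort(tr), val = sort(va),
                               test = sort(te))),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d records, %d classes (train %d / val %d / test %d)\n",
              length(x$records), x$params$config$n_classes,
              length(x$splits$train), length(x$splits$val),
              length(x$splits$test)))
  invisible(x)
}

#' Corrupt a fraction of input feature entries with Gaussian noise
#'
#' Exactly \code{floor(fraction * total)} feature entries — pooled across all
#' structured coordinates and image pixels of all records, chosen uniformly —
#' receive additive Gaussian noise at one empirical standard deviation of
#' their field (structured entries use the structured-pool SD, pixels the
#' pixel-pool SD). Images are re-clipped to [0, 1]; any corrupted entry that
#' would land back on its original value has its noise redrawn so every
#' selected entry differs. Labels, severity and record count are untouched;
#' the input dataset is not modified.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param fraction fraction of entries to corrupt, in [0, 1].
#' @param seed integer seed for the selection and the noise draws.
#' @return a new perturbed \code{synthetic_dataset}.
#' @export
apply_input_noise <- function(dataset, fraction, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  if (fraction == 0) return(dataset)
  set.seed(seed)
  recs <- dataset$records
  # pooled entry index: (record, field, offset)
  sizes <- lapply(recs, function(r)
    c(str = length(r$structured), img = length(r$image)))
  n_str <- vapply(sizes, `[[`, 0, "str")
  n_img <- vapply(sizes, `[[`, 0, "img")
  total <- sum(n_str) + sum(n_img)
  k <- floor(fraction * total)
  if (k == 0L) return(dataset)
  sd_str <- stats::sd(unlist(lapply(recs, `[[`, "structured")))
  sd_img <- stats::sd(unlist(lapply(recs, function(r) as.vector(r$image))))
  chosen <- sample.int(total, k)
  # map pooled index -> (record, field, offset): structured entries first
  cum_str <- cumsum(n_str); cum_img <- cumsum(n_img)
  str_total <- sum(n_str)
  for (ix in chosen) {
    if (ix <= str_total) {
      rec_i <- findInterval(ix - 1L, c(0L, cum_str), rightmost.closed = FALSE)
      off <- ix - c(0L, cum_str)[rec_i]
      old <- recs[[rec_i]]$structured[off]
      recs[[rec_i]]$structured[off] <- old + stats::rnorm(1L, sd = sd_str)
    } else {
      jx <- ix - str_total
      rec_i <- findInterval(jx - 1L, c(0L, cum_img), rightmost.closed = FALSE)
      off <- jx - c(0L, cum_img)[rec_i]
      old <- recs[[rec_i]]$image[off]
      new <- min(max(old + stats::rnorm(1L, sd = sd_img), 0), 1)
      while (new == old)
        new <- min(max(old + stats::rnorm(1L, sd = sd_img), 0), 1)
      recs[[rec_i]]$image[off] <- new
    }
  }
  out <- dataset
  out$records <- recs
  out
}

#' Drop a fraction of the training records
#'
#' Uniformly removes \code{1 - keep_fraction} of the TRAINING split indices;
#' validation and test splits and all record contents are untouched.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param keep_fraction fraction of training records to retain, in (0, 1].
#' @param seed integer seed for the uniform draw.
#' @return a new \code{synthetic_dataset} with a reduced training split.
#' @export
subsample_training <- function(dataset, keep_fraction, seed = 1L) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]")
  if (keep_fraction == 1) return(dataset)
  set.seed(seed)
  tr <- dataset$splits$train
  keep <- sort(sample(tr, floor(keep_fraction * length(tr))))
  out <- dataset
  out$splits$train <- keep
  out
}

#' Remove one modality from a fraction of records
#'
#' Exercises incomplete case records: sets the named modality to absent in a
#' uniformly chosen fraction of records (skipping records where it is the
#' only modality present).
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param modality \code{"structured"}, \code{"text"} or \code{"image"}.
#' @param fraction fraction of records to strip, in [0, 1].
#' @param seed integer seed.
#' @return a new \code{synthetic_dataset}.
#' @export
drop_modality <- function(dataset, modality = c("image", "text", "structured"),
                          fraction = 0.2, seed = 1L) {
  modality <- match.arg(modality)
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  set.seed(seed)
  n <- length(dataset$records)
  hit <- sample.int(n, floor(fraction * n))
  out <- dataset
  for (i in hit) {
    rec <- out$records[[i]]
    if (length(setdiff(record_modalities(rec), modality)) == 0L) next
    rec[[if (modality == "text") "text" else modality]] <- NULL
    out$records[[i]] <- rec
  }
  out
}
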