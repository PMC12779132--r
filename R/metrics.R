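# Multi-label evaluation metrics: subset accuracy, Hamming loss, macro F1,
# one-vs-rest macro AUC-ROC, Jaccard index, and the relative-change /
# absolute-drop arithmetic used for model comparison and robustness tables.

check_label_pair <- function(Y, Yhat) {
  Y <- as.matrix(Y); Yhat <- as.matrix(Yhat)
  if (!all(dim(Y) == dim(Yhat)))
    stop("shape mismatch between truth and prediction")
  if (!all(Y %in% c(0, 1)) || !all(Yhat %in% c(0, 1)))
    stop("label matrices must be binary")
  list(Y = Y, Yhat = Yhat)
}

#' Subset accuracy (exact-match ratio)
#'
#' Fraction of samples whose full predicted label vector matches the truth
#' exactly.
#'
#' @param Y,Yhat N x L binary matrices of true and predicted labels.
#' @return a number in [0, 1].
#' @export
subset_accuracy <- function(Y, Yhat) {
  m <- check_label_pair(Y, Yhat)
  mean(rowSums(m$Y != m$Yhat) == 0L)
}

#' Hamming loss
#'
#' Fraction of the N x L individual label entries predicted wrongly.
#'
#' @inheritParams subset_accuracy
#' @return a number in [0, 1].
#' @export
hamming_loss <- function(Y, Yhat) {
  m <- check_label_pair(Y, Yhat)
  mean(m$Y != m$Yhat)
}

# Per-class confusion counts over label columns.
class_counts <- function(Y, Yhat) {
  tp <- colSums(Y == 1 & Yhat == 1)
  fp <- colSums(Y == 0 & Yhat == 1)
  fn <- colSums(Y == 1 & Yhat == 0)
  list(tp = tp, fp = fp, fn = fn)
}

safe_div <- function(num, den) ifelse(den > 0, num / den, 0)

#' Macro-averaged F1 score with per-class breakdown
#'
#' Per class: precision TP/(TP+FP), recall TP/(TP+FN), F1 their harmonic
#' mean; the macro score is the unweighted mean over classes. Any quantity
#' with a zero denominator is defined as 0.
#'
#' @inheritParams subset_accuracy
#' @param breakdown also return the per-class precision/recall/F1 table.
#' @return the macro F1 in [0, 1], or (with \code{breakdown}) a list
#'   \code{(macro_f1, per_class)}.
#' @export
macro_f1 <- function(Y, Yhat, breakdown = FALSE) {
  m <- check_label_pair(Y, Yhat)
  cc <- class_counts(m$Y, m$Yhat)
  prec <- safe_div(cc$tp, cc$tp + cc$fp)
  rec <- safe_div(cc$tp, cc$tp + cc$fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  if (!breakdown) return(mean(f1))
  list(macro_f1 = mean(f1),
       per_class = data.frame(class = seq_along(f1), tp = cc$tp, fp = cc$fp,
                              fn = cc$fn, precision = prec, recall = rec,
                              f1 = f1))
}

# One-vs-rest AUC for a single label column via the Mann-Whitney rank
# statistic; ties handled by midranks. NA when only one class is present.
auc_column <- function(y, s) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUC-ROC
#'
#' Per label column, the probability that a random positive outscores a
#' random negative (midrank ties counted half), averaged over the columns in
#' which both classes occur. Columns with a single class are excluded from
#' the average.
#'
#' @param Y N x L binary truth matrix.
#' @param S N x L matrix of real-valued per-label scores.
#' @return a number in [0, 1].
#' @export
macro_auc <- function(Y, S) {
  Y <- as.matrix(Y); S <- as.matrix(S)
  if (!all(dim(Y) == dim(S))) stop("shape mismatch between truth and scores")
  if (!all(is.finite(S))) stop("scores must be finite")
  aucs <- vapply(seq_len(ncol(Y)), function(j) auc_column(Y[, j], S[, j]), 0)
  if (all(is.na(aucs)))
    stop("undefined-AUC: no label column has both classes present")
  mean(aucs, na.rm = TRUE)
}

#' Jaccard index for multi-label predictions
#'
#' With \code{average = "samples"} (the default): per sample i, the ratio
#' TP_i / (TP_i + FP_i + FN_i) of the label-set intersection to the union,
#' averaged over the N samples; a sample whose union is empty (truth and
#' prediction both all-zero) contributes 1. With \code{average = "labels"}
#' the same ratio is computed per label column and averaged over columns.
#'
#' @inheritParams subset_accuracy
#' @param average averaging axis, \code{"samples"} or \code{"labels"}.
#' @return a number in [0, 1].
#' @export
jaccard_index <- function(Y, Yhat, average = c("samples", "labels")) {
  average <- match.arg(average)
  m <- check_label_pair(Y, Yhat)
  if (average == "samples") {
    tp <- rowSums(m$Y == 1 & m$Yhat == 1)
    un <- rowSums(m$Y == 1 | m$Yhat == 1)
    mean(ifelse(un > 0, tp / un, 1))
  } else {
    tp <- colSums(m$Y == 1 & m$Yhat == 1)
    un <- colSums(m$Y == 1 | m$Yhat == 1)
    mean(ifelse(un > 0, tp / un, 1))
  }
}

# Round half away from zero to `digits` decimals (matches hand-rounding of
# printed percentages, unlike banker's rounding in round()).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative change between a reference and a new value, in percent
#'
#' \code{100 * |new - reference| / reference}, rounded half-up to one
#' decimal. One convention serves both comparison tables (reference = the
#' baseline model) and ablation tables (reference = the full model).
#'
#' @param reference non-zero reference value.
#' @param new new value.
#' @return percent change, one decimal.
#' @examples
#' relative_change(49.0, 55.2) # 12.7
#' @export
relative_change <- function(reference, new) {
  if (any(reference == 0)) stop("zero reference in relative_change")
  round_half_up(100 * abs(new - reference) / reference, 1L)
}

#' Absolute drop between two values on the printed percentage scale
#'
#' \code{standard - perturbed}, rounded half-up to one decimal; used for
#' robustness rows (e.g. the degradation under input noise).
#'
#' @param standard,perturbed metric values on the percent scale.
#' @return points of drop, one decimal.
#' @examples
#' absolute_drop(64.8, 63.2) # 1.6
#' @export
absolute_drop <- function(standard, perturbed) {
  round_half_up(standard - perturbed, 1L)
}

#' Evaluate all five multi-label metrics
#'
#' @param Y N x L binary truth matrix.
#' @param S N x L real score matrix (for the AUC).
#' @param Yhat N x L binary prediction matrix.
#' @return an object of class \code{metrics_report}: the five metrics on the
#'   [0, 1] scale, the per-class precision/recall/F1 breakdown, and a
#'   \code{percent} vector scaled x100 and rounded to one decimal (Hamming
#'   loss appears on both scales).
#' @export
evaluate_all <- function(Y, S, Yhat) {
  f1 <- macro_f1(Y, Yhat, breakdown = TRUE)
  rep <- list(subset_accuracy = subset_accuracy(Y, Yhat),
              macro_f1 = f1$macro_f1,
              macro_auc = macro_auc(Y, S),
              jaccard = jaccard_index(Y, Yhat),
              hamming_loss = hamming_loss(Y, Yhat),
              per_class = f1$per_class)
  rep$percent <- c(`Subset Accuracy(%)` = round_half_up(100 * rep$subset_accuracy),
                   `Macro F1(%)` = round_half_up(100 * rep$macro_f1),
                   `Macro AUC-ROC` = round_half_up(100 * rep$macro_auc),
                   `Jaccard Index(%)` = round_half_up(100 * rep$jaccard),
                   `Hamming Loss(%)` = round_half_up(100 * rep$hamming_loss))
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$percent)
  cat(sprintf("  (hamming loss as fraction: %.4g)\n", x$hamming_loss))
  invisible(x)
}

#' Write a metrics comparison table as CSV
#'
#' One row per model/setting/dataset with the standard five metric columns on
#' the percent scale.
#'
#' @param rows data frame with columns \code{Model}, \code{Dataset},
#'   \code{Setting} and the five percent-scale metric columns.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_metrics_csv <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# Turn a metrics_report into one table row.
report_row <- function(report, model = "model", dataset = "synthetic",
                       setting = "Standard") {
  cbind(data.frame(Model = model, Dataset = dataset, Setting = setting),
        as.data.frame(as.list(report$percent), check.names = FALSE))
}
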