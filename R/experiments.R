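# Robustness and ablation harness: train/evaluate the model under the
# standard, input-noise and reduced-data settings, and under module-removal
# configurations, reporting the comparison arithmetic on the percent scale.

train_and_eval <- function(model_cfg, train_cfg, dataset, n_classes,
                           structured_dim, split = "test") {
  model <- build_model(model_cfg, n_classes, structured_dim,
                       seed = train_cfg$seed)
  fit <- train_model(model, dataset, train_cfg)
  list(fit = fit, report = evaluate_model(fit$model, dataset, split))
}

dataset_dims <- function(dataset) {
  list(n_classes = length(dataset$records[[1]]$labels),
       structured_dim = length(dataset$records[[1]]$structured))
}

#' Train and evaluate under standard / input-noise / reduced-data settings
#'
#' Runs the three robustness settings: \code{Standard} (the dataset as is),
#' \code{+20\% Noise} (a fraction of pooled input feature entries corrupted
#' by \code{\link{apply_input_noise}}), and \code{-30\% Data} (the training
#' split reduced by \code{\link{subsample_training}}). A model is trained
#' and evaluated per setting (and per seed); metrics are averaged over seeds
#' and the per-metric absolute drops from the Standard row are reported.
#'
#' @param model_cfg a \code{\link{model_config}}.
#' @param train_cfg a \code{\link{train_config}}; its seed is replaced by
#'   each element of \code{seeds}.
#' @param dataset a \code{synthetic_dataset}.
#' @param noise_fraction fraction of feature entries corrupted in the noise
#'   setting.
#' @param keep_fraction training fraction kept in the reduced-data setting.
#' @param seeds integer vector of training seeds to average over.
#' @return list: \code{table} (one row per setting, Table-style percent
#'   columns averaged over seeds), \code{drops} (absolute percent-point drop
#'   of each perturbed setting vs Standard, per metric), \code{per_seed}
#'   (raw per-seed rows).
#' @export
run_robustness <- function(model_cfg, train_cfg, dataset,
                           noise_fraction = 0.2, keep_fraction = 0.7,
                           seeds = train_cfg$seed) {
  dims <- dataset_dims(dataset)
  settings <- list(
    "Standard" = function(seed) dataset,
    "+20% Noise" = function(seed) apply_input_noise(dataset, noise_fraction,
                                                    seed = seed + 1000L),
    "-30% Data" = function(seed) subsample_training(dataset, keep_fraction,
                                                    seed = seed + 2000L))
  per_seed <- list()
  for (seed in seeds) {
    for (snm in names(settings)) {
      tc <- train_cfg; tc$seed <- as.integer(seed)
      ds <- settings[[snm]](as.integer(seed))
      res <- train_and_eval(model_cfg, tc, ds, dims$n_classes,
                            dims$structured_dim)
      row <- report_row(res$report, model = "full", setting = snm)
      row$Seed <- seed
      per_seed[[length(per_seed) + 1L]] <- row
    }
  }
  per_seed <- do.call(rbind, per_seed)
  metric_cols <- setdiff(names(per_seed),
                         c("Model", "Dataset", "Setting", "Seed"))
  tab <- stats::aggregate(per_seed[metric_cols],
                          by = list(Setting = per_seed$Setting), FUN = mean)
  tab <- tab[match(names(settings), tab$Setting), ]
  std <- tab[tab$Setting == "Standard", metric_cols]
  drops <- lapply(setdiff(names(settings), "Standard"), function(snm) {
    pert <- tab[tab$Setting == snm, metric_cols]
    data.frame(Setting = snm,
               t(vapply(metric_cols, function(mc)
                 absolute_drop(std[[mc]], pert[[mc]]), 0)),
               check.names = FALSE)
  })
  drops <- do.call(rbind, drops)
  names(drops)[-1] <- metric_cols
  tab <- cbind(Model = "full", Dataset = "synthetic", tab)
  list(table = tab, drops = drops, per_seed = per_seed)
}

#' Ablation study: remove modules and compare against the full model
#'
#' Trains one model per switch combination (plus the full model), evaluates
#' on the named split and appends the relative change of every metric versus
#' the full model.
#'
#' @param base_cfg a \code{\link{model_config}} with all switches on.
#' @param train_cfg a \code{\link{train_config}}.
#' @param dataset a \code{synthetic_dataset}.
#' @param combos named list of character vectors of switches to turn off;
#'   the default mirrors single-module removal of \code{causal_mask},
#'   \code{pcma} and \code{mtl}.
#' @param split evaluation split.
#' @param seeds training seeds to average over.
#' @return list: \code{table} (full model first, then one row per combo,
#'   percent metrics averaged over seeds), \code{relative} (relative change
#'   vs the full model per metric), \code{val_accuracy} (per-seed validation
#'   subset accuracy by model).
#' @export
run_ablation <- function(base_cfg, train_cfg, dataset,
                         combos = list("W/o Causal Masked Attention" = "causal_mask",
                                       "W/o PCMA Fusion" = "pcma",
                                       "W/o Multi-task Learning Optimization" = "mtl"),
                         split = "test", seeds = train_cfg$seed) {
  dims <- dataset_dims(dataset)
  variants <- c(list("full" = character(0)), combos)
  rows <- list(); val_rows <- list()
  for (vn in names(variants)) {
    cfg <- base_cfg
    for (sw in variants[[vn]]) {
      if (!sw %in% names(cfg$switches)) stop("unknown switch: ", sw)
      cfg$switches[[sw]] <- FALSE
    }
    for (seed in seeds) {
      tc <- train_cfg; tc$seed <- as.integer(seed)
      res <- train_and_eval(cfg, tc, dataset, dims$n_classes,
                            dims$structured_dim, split = split)
      row <- report_row(res$report, model = vn)
      row$Seed <- seed
      rows[[length(rows) + 1L]] <- row
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(Model = vn, Seed = seed,
                   val_subset_accuracy = max(res$fit$history$val_subset_accuracy))
    }
  }
  rows <- do.call(rbind, rows)
  metric_cols <- setdiff(names(rows), c("Model", "Dataset", "Setting", "Seed"))
  tab <- stats::aggregate(rows[metric_cols], by = list(Model = rows$Model),
                          FUN = mean)
  tab <- tab[match(names(variants), tab$Model), ]
  full <- tab[tab$Model == "full", metric_cols]
  rel <- lapply(setdiff(names(variants), "full"), function(vn) {
    v <- tab[tab$Model == vn, metric_cols]
    data.frame(Model = vn,
               t(vapply(metric_cols, function(mc)
                 if (full[[mc]] == 0) NA_real_   # relative change undefined
                 else relative_change(full[[mc]], v[[mc]]), 0)),
               check.names = FALSE)
  })
  rel <- do.call(rbind, rel)
  names(rel)[-1] <- metric_cols
  list(table = cbind(Dataset = "synthetic", tab), relative = rel,
       val_accuracy = do.call(rbind, val_rows))
}

#' Pairwise relative-change comparison report
#'
#' For every (baseline, model) row pair in a metrics table, emits the
#' relative change of each metric with one-decimal rounding.
#'
#' @param rows data frame with a key column (\code{Model}, or
#'   \code{Setting} when the models are identical) and numeric metric
#'   columns (percent scale).
#' @param baseline key values to use as references (default: every row
#'   except the first is compared against the first).
#' @param key the column identifying rows; by default \code{Model}, or
#'   \code{Setting} when \code{Model} carries a single value.
#' @return data frame with columns \code{Baseline}, \code{Model}, and one
#'   relative-change column per metric.
#' @export
report_comparison <- function(rows, baseline = NULL, key = NULL) {
  if (is.null(key)) {
    key <- "Model"
    if ((is.null(rows$Model) || length(unique(rows$Model)) == 1L) &&
        !is.null(rows$Setting))
      key <- "Setting"
  }
  if (is.null(rows[[key]])) stop("rows lack a '", key, "' column")
  metric_cols <- names(rows)[vapply(rows, is.numeric, TRUE)]
  metric_cols <- setdiff(metric_cols, "Seed")
  if (is.null(baseline)) baseline <- rows[[key]][1]
  out <- list()
  for (bnm in baseline) {
    b <- rows[rows[[key]] == bnm, , drop = FALSE][1, ]
    for (i in seq_len(nrow(rows))) {
      if (rows[[key]][i] == bnm) next
      out[[length(out) + 1L]] <- data.frame(
        Baseline = bnm, Model = rows[[key]][i],
        t(vapply(metric_cols, function(mc)
          if (b[[mc]] == 0) NA_real_             # relative change undefined
          else relative_change(b[[mc]], rows[i, mc]), 0)),
        check.names = FALSE)
    }
  }
  if (length(out) == 0L)
    stop("nothing to compare: all rows share the same '", key, "' value")
  res <- do.call(rbind, out)
  names(res)[-(1:2)] <- metric_cols
  res
}
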