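# Evaluation metrics, the labeled-prevalence sweep, and the ablation
# harness, all runnable end-to-end on synthetic data.

#' Classification metrics for DDI predictions
#'
#' Count metrics threshold the positive-class probability at `threshold`;
#' AUROC is computed from midranks (ties share their average rank) and AUPR
#' by step integration of the precision-recall curve with tied scores
#' processed as one group.  With a single-class label vector the ranking
#' metrics are undefined and reported as `NA` with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores positive-class scores.
#' @param threshold decision threshold on the score.
#' @return a `metric_report` list: accuracy, precision, recall, f1, auroc,
#'   aupr, n.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("single-class labels: AUROC/AUPR undefined", call. = FALSE)
    auroc <- NA_real_
    aupr <- NA_real_
  } else {
    rk <- rank(scores)  # midranks
    auroc <- (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aupr <- average_precision(labels, scores)
  }
  structure(list(accuracy = (tp + tn) / length(labels),
                 precision = precision, recall = recall, f1 = f1,
                 auroc = auroc, aupr = aupr, n = length(labels)),
            class = "metric_report")
}

# step integration of the PR curve: sum over descending score groups of
# (delta recall) * (precision at that cut)
average_precision <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- which(diff(sc) != 0)
  cuts <- c(grp_end, length(sc))
  tp <- cumsum(lab)[cuts]
  pos_cum <- seq_along(lab)[cuts]
  prec <- tp / pos_cum
  rec <- tp / sum(lab)
  sum(diff(c(0, rec)) * prec)
}

#' Correlation metrics for DDS predictions
#'
#' Pearson product-moment and Spearman rank correlation (ties midranked).
#' Constant vectors make a correlation undefined; it is returned as `NA`
#' with a warning.
#'
#' @param predicted,target numeric vectors (length >= 3).
#' @return list with `pearson` and `spearman`.
#' @export
compute_correlations <- function(predicted, target) {
  stopifnot(length(predicted) == length(target))
  if (length(predicted) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(predicted) == 0 || stats::sd(target) == 0) {
    warning("constant vector: correlations undefined", call. = FALSE)
    return(list(pearson = NA_real_, spearman = NA_real_))
  }
  list(pearson = stats::cor(predicted, target, method = "pearson"),
       spearman = stats::cor(predicted, target, method = "spearman"))
}

#' Stratified train/test split of labeled pairs
#'
#' A fixed fraction of pairs is held out, stratified by the DDI label so
#' both classes appear in the test split.
#'
#' @param pairs data.frame of labeled pairs.
#' @param test_fraction held-out fraction (default 0.2).
#' @param seed split seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_pairs <- function(pairs, test_fraction = 0.2, seed = 1L) {
  set.seed(seed)
  strat <- ifelse(is.na(pairs$ddi), 2L, pairs$ddi)
  test_ix <- unlist(lapply(unique(strat), function(s) {
    ix <- which(strat == s)
    sample(ix, round(length(ix) * test_fraction))
  }), use.names = FALSE)
  list(train = pairs[-test_ix, , drop = FALSE],
       test = pairs[test_ix, , drop = FALSE])
}

#' Train on given pairs and evaluate on a fixed test split
#'
#' @param dataset a `kmr_dataset`.
#' @param train_pairs,test_pairs pair data.frames with DDI labels.
#' @param config a [kmr_config()].
#' @param seed training seed.
#' @param channels optional precomputed taxonomy channels.
#' @return list with `metrics` (a `metric_report`), `fit` (the [train_ddi()]
#'   result) and `scores`.
#' @export
train_eval_ddi <- function(dataset, train_pairs, test_pairs,
                           config = kmr_config(), seed = config$seed,
                           channels = NULL) {
  fit <- train_ddi(dataset, config, seed = seed, train_pairs = train_pairs,
                   channels = channels)
  scores <- predict_ddi(fit$model, fit$inputs, test_pairs)
  list(metrics = compute_metrics(test_pairs$ddi, scores),
       fit = fit, scores = scores)
}

#' Labeled-prevalence sweep
#'
#' Trains on random subsamples of the training pairs at each fraction
#' (default 5, 15, 25, 50, 75, 85 and 100 percent) and evaluates every
#' model on the same fixed test split, which is never subsampled.  With
#' `sweep_positive_only` only positive pairs are subsampled and all
#' negatives kept.
#'
#' @param dataset a `kmr_dataset`.
#' @param fractions percentages of the training set to keep.
#' @param seeds one training run per seed per fraction.
#' @param config a [kmr_config()].
#' @param test_fraction held-out fraction for the fixed split.
#' @param split_seed seed of the fixed split (constant across the sweep).
#' @return data.frame, one row per fraction x seed, with the
#'   classification metrics.
#' @export
prevalence_sweep <- function(dataset,
                             fractions = c(5, 15, 25, 50, 75, 85, 100),
                             seeds = 1:5, config = kmr_config(),
                             test_fraction = 0.2, split_seed = 2024L) {
  pairs <- dataset$pairs[!is.na(dataset$pairs$ddi), , drop = FALSE]
  sp <- split_pairs(pairs, test_fraction, split_seed)
  rows <- list()
  for (seed in seeds) {
    channels <- learn_class_channels(dataset$taxonomy, config, seed)
    for (frac in fractions) {
      set.seed(seed * 10000L + round(frac))
      tr <- sp$train
      if (frac < 100) {
        if (config$sweep_positive_only) {
          pos <- which(tr$ddi == 1L)
          keep_pos <- sample(pos, max(1L, round(length(pos) * frac / 100)))
          keep <- sort(c(keep_pos, which(tr$ddi == 0L)))
        } else {
          keep <- sort(sample(nrow(tr), max(1L, round(nrow(tr) * frac / 100))))
        }
        tr <- tr[keep, , drop = FALSE]
      }
      if (nrow(tr) < 1L || length(unique(tr$ddi)) < 2L) {
        message("fraction ", frac, "%, seed ", seed,
                ": too few training pairs, skipped")
        next
      }
      res <- train_eval_ddi(dataset, tr, sp$test, config, seed = seed,
                            channels = channels)
      m <- res$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = frac, seed = seed, n_train = nrow(tr),
        accuracy = m$accuracy, precision = m$precision, recall = m$recall,
        f1 = m$f1, auroc = m$auroc, aupr = m$aupr)
    }
  }
  do.call(rbind, rows)
}

#' Ablation run: drop one feature block
#'
#' Re-trains and evaluates with the named block zeroed before fusion
#' (`"none"` reproduces the standard pipeline bit-for-bit).
#'
#' @param dataset a `kmr_dataset`.
#' @param drop `"none"`, `"pharmacology"`, `"drug_class"` or
#'   `"textual_description"`.
#' @param config a [kmr_config()].
#' @param seed training seed.
#' @param test_fraction,split_seed fixed-split parameters (match
#'   [prevalence_sweep()] defaults).
#' @param channels optional precomputed taxonomy channels.
#' @return a `metric_report`.
#' @export
ablation <- function(dataset, drop = "none", config = kmr_config(),
                     seed = config$seed, test_fraction = 0.2,
                     split_seed = 2024L, channels = NULL) {
  if (!drop %in% c("none", "pharmacology", "drug_class", "textual_description")) {
    stop("unknown ablation family '", drop, "'", call. = FALSE)
  }
  cfg <- config
  cfg$ablate <- drop
  pairs <- dataset$pairs[!is.na(dataset$pairs$ddi), , drop = FALSE]
  sp <- split_pairs(pairs, test_fraction, split_seed)
  train_eval_ddi(dataset, sp$train, sp$test, cfg, seed = seed,
                 channels = channels)$metrics
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in setdiff(names(x), "n")) {
    cat(sprintf("  %-10s %.4f\n", nm, x[[nm]]))
  }
  cat("  n         ", x$n, "\n")
  invisible(x)
}
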