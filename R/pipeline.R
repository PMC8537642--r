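# End-to-end evaluation: repeated grouped partitions, training, per-run
# re-ranking of test-side parents, pooled rank percentiles against a seeded
# random-permutation baseline, PR-AUC per repeat, and a paired signed-rank
# comparison of the two rankings.

# Seeded random-permutation baseline: same parents, ranks drawn uniformly
# per docking run.
random_baseline_ranking <- function(ranking, seed) {
  set.seed(seed)
  run <- interaction(ranking$complex_id, ranking$docking_mode, drop = TRUE)
  pieces <- lapply(split(ranking, run), function(g) {
    g$rank <- sample(nrow(g))
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Evaluate averaged-probability re-ranking on a pose dataset
#'
#' For each repeated grouped 80/20 partition: trains the nativeness
#' classifier on training-side complexes, predicts native-like probabilities
#' for test-side refined poses, re-ranks test-side parents by averaged child
#' probability, and records the PR-AUC over test refined poses.  Ranks of
#' native-like parents (a parent is native-like iff its own DockQ >= 0.23)
#' are pooled over repeats and summarised as median / 75th / 95th
#' percentiles, next to a seeded random-permutation baseline on the same
#' runs; the two paired rank lists are compared with the Wilcoxon
#' matched-pairs signed-rank test.
#'
#' @param ds A [pose_dataset()] whose meta carries `parent_label`.
#' @param n_repeats Number of repeated partitions (default 5).
#' @param train_frac Training fraction of complexes (default 0.8).
#' @param seed Base seed for splits, training and the baseline.
#' @param hyperparams Passed to [train_nativeness()].
#' @param scale_pos_weight Passed to [train_nativeness()].
#' @return An `eval_report`: list with `per_repeat` (data frame: repeat,
#'   `pr_auc`, n test poses/parents), `rankings` (list of test ranking
#'   tables), `model_stats` and `baseline_stats` (from [rank_statistics()]),
#'   `wilcoxon_p`, `best_repeat` (highest PR-AUC) and `models`.
#' @export
evaluate_reranking <- function(ds, n_repeats = 5L, train_frac = 0.8, seed = 0L,
                               hyperparams = list(), scale_pos_weight = "auto") {
  splits <- make_splits(unique(ds$meta$complex_id), n_repeats, train_frac, seed)
  per <- list(); rankings <- list(); baselines <- list(); models <- list()
  for (sp in splits) {
    model <- train_nativeness(ds, sp, hyperparams, seed = sp$seed,
                              scale_pos_weight = scale_pos_weight)
    test <- ds$meta$complex_id %in% sp$test_complexes
    prob <- predict_nativeness(model, ds$X[test, , drop = FALSE])
    mf <- ds$meta[test, , drop = FALSE]
    rt <- rerank(prob, mf)
    auc <- if (length(unique(mf$label)) == 2L) pr_auc(mf$label, prob) else NA_real_
    rankings[[sp$repeat_index]] <- rt
    baselines[[sp$repeat_index]] <- random_baseline_ranking(rt, sp$seed + 10000L)
    models[[sp$repeat_index]] <- model
    per[[sp$repeat_index]] <- data.frame(
      repeat_index = sp$repeat_index, pr_auc = auc,
      n_test_poses = sum(test), n_test_parents = nrow(rt),
      n_test_native_parents = sum(rt$parent_label == 1)
    )
  }
  per <- do.call(rbind, per)
  model_stats <- rank_statistics(rankings)
  baseline_stats <- rank_statistics(baselines)
  # pair model vs baseline rank per native-like parent, pooled over repeats
  paired_a <- unlist(lapply(rankings, function(rt) {
    ord <- order(rt$complex_id, rt$docking_mode, rt$parent_id)
    rt$rank[ord][rt$parent_label[ord] == 1]
  }))
  paired_b <- unlist(lapply(baselines, function(rt) {
    ord <- order(rt$complex_id, rt$docking_mode, rt$parent_id)
    rt$rank[ord][rt$parent_label[ord] == 1]
  }))
  wilcoxon_p <- compare_rankings(paired_a, paired_b)
  structure(list(
    per_repeat = per, rankings = rankings, baselines = baselines,
    model_stats = model_stats, baseline_stats = baseline_stats,
    wilcoxon_p = wilcoxon_p,
    best_repeat = per$repeat_index[which.max(per$pr_auc)],
    models = models, splits = splits
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    paste0("eval_report: %d repeats, %d pooled native-like parent ranks\n",
           "  model    median %.1f  p75 %.1f  p95 %.1f\n",
           "  baseline median %.1f  p75 %.1f  p95 %.1f\n",
           "  Wilcoxon p = %.3g; PR-AUC per repeat: %s\n"),
    nrow(x$per_repeat), x$model_stats$n,
    x$model_stats$median, x$model_stats$p75, x$model_stats$p95,
    x$baseline_stats$median, x$baseline_stats$p75, x$baseline_stats$p95,
    x$wilcoxon_p, paste(sprintf("%.3f", x$per_repeat$pr_auc), collapse = ", ")
  ))
  invisible(x)
}

#' Attribution on the test side of the best repeat
#'
#' Runs additive attribution with the best-PR-AUC model over its own test
#' poses, mirroring the practice of interpreting the strongest
#' cross-validated model.
#'
#' @param report An `eval_report` from [evaluate_reranking()].
#' @param ds The [pose_dataset()] the report was computed on.
#' @return See [attribute()].
#' @export
attribute_best <- function(report, ds) {
  sp <- report$splits[[report$best_repeat]]
  test <- ds$meta$complex_id %in% sp$test_complexes
  attribute(report$models[[report$best_repeat]], ds$X[test, , drop = FALSE])
}
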