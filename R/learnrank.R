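# Grouped partitioning, the gradient-boosted nativeness classifier, the
# averaged-probability parent re-ranking rule, evaluation statistics
# (rank percentiles, PR-AUC, paired signed-rank comparison) and additive
# per-feature attribution.

#' Grouped 80/20 train/test partitions by complex id
#'
#' Repeated seeded random partitions of complex ids (never of poses), so no
#' refined pose of one complex can sit on both sides of any split.
#'
#' @param complex_ids Character vector of complex ids (duplicates allowed;
#'   uniqued internally).
#' @param n_repeats Number of repeated partitions (default 5).
#' @param train_frac Fraction of complexes on the training side (default 0.8).
#' @param seed Base RNG seed; repeat `i` uses `seed + i - 1`.
#' @return List of `dataset_split` objects with `repeat_index`,
#'   `train_complexes`, `test_complexes`, `seed`.
#' @export
make_splits <- function(complex_ids, n_repeats = 5L, train_frac = 0.8, seed = 0L) {
  ids <- sort(unique(as.character(complex_ids)))
  n <- length(ids)
  if (n < n_repeats) {
    abort(sprintf("need at least %d complexes, got %d", n_repeats, n),
          "nbrank_size_error")
  }
  n_train <- round(train_frac * n)
  n_train <- max(1L, min(n - 1L, n_train))
  lapply(seq_len(n_repeats), function(i) {
    set.seed(seed + i - 1L)
    tr <- sort(sample(ids, n_train))
    structure(list(repeat_index = i, train_complexes = tr,
                   test_complexes = setdiff(ids, tr), seed = seed + i - 1L),
              class = "dataset_split")
  })
}

default_hyperparams <- function() {
  list(nrounds = 300L, max_depth = 6L, eta = 0.1, subsample = 0.8)
}

#' Train the gradient-boosted nativeness classifier
#'
#' Fits an XGBoost binary classifier (logistic objective) mapping the feature
#' vector of each refined pose to its nativeness label, using only poses of
#' training-side complexes.  Missing feature values (`NA`) are handled
#' natively by the trees.  Class imbalance is countered by a positive-class
#' weight, `n_negative / n_positive` on the training side by default.
#' Deterministic given data, hyperparameters and seed (single-threaded).
#'
#' @param ds A [pose_dataset()].
#' @param split A `dataset_split` (from [make_splits()]), or `NULL` to train
#'   on all complexes.
#' @param hyperparams List with `nrounds`, `max_depth`, `eta`, `subsample`
#'   (defaults 300, 6, 0.1, 0.8).
#' @param seed RNG seed for tree construction.
#' @param scale_pos_weight `"auto"` (n_neg/n_pos), a number, or `NULL` to
#'   disable weighting.
#' @return A `nativeness_model`.
#' @export
train_nativeness <- function(ds, split = NULL, hyperparams = list(), seed = 0L,
                             scale_pos_weight = "auto") {
  hp <- utils::modifyList(default_hyperparams(), hyperparams)
  idx <- if (is.null(split)) seq_len(nrow(ds$meta)) else
    which(ds$meta$complex_id %in% split$train_complexes)
  y <- ds$meta$label[idx]
  if (length(unique(y)) < 2L) {
    abort("training data must contain both nativeness labels",
          "nbrank_degenerate_labels")
  }
  spw <- if (identical(scale_pos_weight, "auto")) sum(y == 0) / sum(y == 1)
         else if (is.null(scale_pos_weight)) 1 else as.numeric(scale_pos_weight)
  params <- list(
    objective = "binary:logistic",
    max_depth = hp$max_depth, eta = hp$eta, subsample = hp$subsample,
    scale_pos_weight = spw, nthread = 1L, seed = seed
  )
  dtrain <- xgboost::xgb.DMatrix(ds$X[idx, , drop = FALSE], label = y, missing = NA)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = hp$nrounds, verbose = 0)
  structure(list(
    booster = booster,
    feature_names = colnames(ds$X),
    hyperparams = hp, seed = seed, scale_pos_weight = spw,
    train_complexes = if (is.null(split)) unique(ds$meta$complex_id)
                      else split$train_complexes
  ), class = "nativeness_model")
}

check_schema_match <- function(model, X) {
  if (!identical(colnames(X), model$feature_names)) {
    abort("feature columns do not match the model's schema fingerprint",
          "nbrank_schema_error")
  }
}

#' Predict native-like probabilities for refined poses
#'
#' @param model A `nativeness_model`.
#' @param ds A [pose_dataset()] (or a feature matrix with matching columns).
#' @param margin Return log-odds instead of probabilities (default `FALSE`).
#' @return Numeric vector, one probability in \[0, 1\] per refined pose
#'   (empty input gives an empty vector).
#' @export
predict_nativeness <- function(model, ds, margin = FALSE) {
  X <- if (inherits(ds, "pose_dataset")) ds$X else as.matrix(ds)
  check_schema_match(model, X)
  if (nrow(X) == 0L) return(numeric(0))
  stats::predict(model$booster, xgboost::xgb.DMatrix(X, missing = NA),
                 outputmargin = margin)
}

#' Re-rank parent poses by averaged child probability
#'
#' Each parent's score is the arithmetic mean of the predicted native-like
#' probabilities of its refined children; parents are sorted in descending
#' order of that mean within each docking run (complex x docking mode).
#' Ties are broken deterministically by the maximum child probability, then
#' by parent id.
#'
#' @param probabilities Numeric vector, one per refined pose.
#' @param manifest Data frame aligned with `probabilities`, columns
#'   `complex_id`, `docking_mode`, `parent_id` (and optionally
#'   `parent_dockq`/`parent_label` carried through).
#' @param parents Optional character vector of all parent ids expected in the
#'   run; a listed parent with no refined child raises an empty-group error.
#' @return A `ranking_table` data frame: one row per parent with
#'   `complex_id`, `docking_mode`, `parent_id`, `mean_prob`, `max_prob`,
#'   `rank` (1-based within the run) and, when available, `parent_label`.
#' @export
rerank <- function(probabilities, manifest, parents = NULL) {
  if (length(probabilities) != nrow(manifest)) {
    abort("probabilities and manifest are not aligned", "nbrank_invalid_argument")
  }
  if (!is.null(parents) && !all(parents %in% manifest$parent_id)) {
    abort("parent with zero refined poses", "nbrank_empty_group")
  }
  key <- interaction(manifest$complex_id, manifest$docking_mode,
                     manifest$parent_id, drop = TRUE)
  agg <- data.frame(
    complex_id = tapply(as.character(manifest$complex_id), key, `[`, 1),
    docking_mode = tapply(as.character(manifest$docking_mode), key, `[`, 1),
    parent_id = tapply(as.character(manifest$parent_id), key, `[`, 1),
    mean_prob = as.numeric(tapply(probabilities, key, mean)),
    max_prob = as.numeric(tapply(probabilities, key, max)),
    stringsAsFactors = FALSE
  )
  if (!is.null(manifest$parent_label)) {
    agg$parent_label <- as.integer(tapply(manifest$parent_label, key, `[`, 1))
  }
  if (!is.null(manifest$parent_dockq)) {
    agg$parent_dockq <- as.numeric(tapply(manifest$parent_dockq, key, `[`, 1))
  }
  run <- interaction(agg$complex_id, agg$docking_mode, drop = TRUE)
  pieces <- lapply(split(agg, run), function(g) {
    ord <- order(-g$mean_prob, -g$max_prob, g$parent_id)
    g <- g[ord, , drop = FALSE]
    g$rank <- seq_len(nrow(g))
    g
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Pooled rank percentiles of native-like parents
#'
#' Pools the ranks of native-like parents over one or more ranking tables and
#' reports median, 75th and 95th percentile (type-7 linear-interpolation
#' quantiles).
#'
#' @param rankings A `ranking_table` or list of them, each with a
#'   `parent_label` column (1 = native-like).
#' @return List with `ranks` (pooled rank vector), `n`, `median`, `p75`,
#'   `p95`.
#' @export
rank_statistics <- function(rankings) {
  if (inherits(rankings, "data.frame")) rankings <- list(rankings)
  ranks <- unlist(lapply(rankings, function(rt) {
    if (is.null(rt$parent_label)) {
      abort("ranking table lacks a parent_label column", "nbrank_invalid_argument")
    }
    rt$rank[rt$parent_label == 1]
  }), use.names = FALSE)
  if (length(ranks) == 0L) {
    abort("no native-like parents in any ranking", "nbrank_empty_population")
  }
  q <- stats::quantile(ranks, c(0.5, 0.75, 0.95), type = 7, names = FALSE)
  list(ranks = ranks, n = length(ranks), median = q[1], p75 = q[2], p95 = q[3])
}

#' Area under the precision-recall curve
#'
#' Average-precision form: thresholds sweep the distinct scores in descending
#' order and the area is the sum of precision times incremental recall.
#' Constant scores therefore give the class prevalence.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param scores Numeric scores, higher = more positive.
#' @return Area in \[0, 1\].
#' @export
pr_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    abort("labels and scores are not aligned", "nbrank_invalid_argument")
  }
  npos <- sum(labels == 1)
  if (npos == 0L || npos == length(labels)) {
    abort("PR-AUC needs both classes", "nbrank_degenerate_labels")
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  last <- !duplicated(sc, fromLast = TRUE)  # threshold boundaries (tie groups)
  tp <- cumsum(lab)[last]
  n_pred <- seq_along(lab)[last]
  recall <- tp / npos
  precision <- tp / n_pred
  sum(diff(c(0, recall)) * precision)
}

#' Paired Wilcoxon signed-rank comparison of two rankings
#'
#' Two-sided matched-pairs signed-rank test on paired rank lists.
#' Zero differences are dropped (p = 1 if all are zero); the exact
#' distribution is used for up to 25 zero-excluded untied pairs, otherwise a
#' normal approximation with continuity and tie corrections.
#'
#' @param ranks_a,ranks_b Paired numeric vectors of equal length (>= 5).
#' @return Two-sided p-value.
#' @export
compare_rankings <- function(ranks_a, ranks_b) {
  if (length(ranks_a) != length(ranks_b)) {
    abort("rank lists must be paired (equal length)", "nbrank_pairing_error")
  }
  if (length(ranks_a) < 5L) {
    abort("need at least 5 pairs", "nbrank_pairing_error")
  }
  d <- ranks_a - ranks_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1.0)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 25L) {
    p <- 2 * min(stats::psignrank(V, n),
                 stats::psignrank(V - 1, n, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Additive (SHAP-style) feature attribution on a pose set
#'
#' Per-sample signed feature contributions from the tree ensemble
#' (TreeSHAP).  Contributions are on the log-odds (margin) scale and satisfy
#' `base + sum(contributions) = margin prediction` for every sample.  Global
#' importance is the mean absolute contribution per feature, in descending
#' order.
#'
#' @param model A `nativeness_model`.
#' @param ds A [pose_dataset()] or feature matrix.
#' @return List with `contributions` (n x p matrix), `base` (per-sample bias
#'   term) and `importance` (data frame `feature`, `mean_abs`, sorted
#'   descending).
#' @export
attribute <- function(model, ds) {
  X <- if (inherits(ds, "pose_dataset")) ds$X else as.matrix(ds)
  check_schema_match(model, X)
  ctr <- stats::predict(model$booster, xgboost::xgb.DMatrix(X, missing = NA),
                        predcontrib = TRUE)
  p <- length(model$feature_names)
  contributions <- ctr[, seq_len(p), drop = FALSE]
  colnames(contributions) <- model$feature_names
  imp <- colMeans(abs(contributions))
  importance <- data.frame(feature = names(imp), mean_abs = as.numeric(imp),
                           stringsAsFactors = FALSE)
  importance <- importance[order(-importance$mean_abs, importance$feature), ]
  rownames(importance) <- NULL
  list(contributions = contributions, base = ctr[, p + 1L],
       importance = importance)
}
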