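test_that("grouped splits are seeded, sized and leak-free", {
  ids <- sprintf("C%02d", 1:10)
  splits <- make_splits(ids, n_repeats = 5, train_frac = 0.8, seed = 1)
  expect_length(splits, 5)
  for (sp in splits) {
    expect_length(sp$train_complexes, 8)
    expect_length(sp$test_complexes, 2)
    expect_length(intersect(sp$train_complexes, sp$test_complexes), 0)
    expect_setequal(c(sp$train_complexes, sp$test_complexes), ids)
  }
  expect_identical(make_splits(ids, 5, 0.8, seed = 1), splits)
  expect_false(identical(make_splits(ids, 5, 0.8, seed = 2), splits))
  expect_error(make_splits(ids[1:3], n_repeats = 5), class = "nbrank_size_error")

  # the split RNG is plain sampling of ids: reproduce repeat 3 by hand
  set.seed(1 + 2)
  expect_equal(splits[[3]]$train_complexes, sort(sample(ids, 8)))
})

test_that("training separates separable synthetic data deterministically", {
  ds <- toy_dataset(n_complexes = 6, poses_per_complex = 8, separation = 5)
  splits <- make_splits(unique(ds$meta$complex_id), n_repeats = 2, seed = 0)
  model <- train_nativeness(ds, splits[[1]], seed = 0)
  train_idx <- ds$meta$complex_id %in% splits[[1]]$train_complexes
  prob <- predict_nativeness(model, ds$X[train_idx, , drop = FALSE])
  expect_equal(as.integer(prob > 0.5), ds$meta$label[train_idx])
  # positives score above 0.5 on held-out complexes too
  test_idx <- !train_idx
  prob_test <- predict_nativeness(model, ds$X[test_idx, , drop = FALSE])
  expect_true(all(prob_test[ds$meta$label[test_idx] == 1] > 0.5))
  expect_true(all(prob_test >= 0 & prob_test <= 1))

  # determinism: identical predictions from an identical retrain
  model2 <- train_nativeness(ds, splits[[1]], seed = 0)
  expect_identical(predict_nativeness(model2, ds$X), predict_nativeness(model, ds$X))

  # degenerate labels
  ds_one <- ds; ds_one$meta$label <- 1L
  expect_error(train_nativeness(ds_one, splits[[1]]),
               class = "nbrank_degenerate_labels")

  # schema mismatch and empty input
  expect_error(predict_nativeness(model, ds$X[, rev(colnames(ds$X))]),
               class = "nbrank_schema_error")
  expect_length(predict_nativeness(model, ds$X[0, , drop = FALSE]), 0)
})

test_that("models accept records with entirely missing energy blocks", {
  ds <- toy_dataset(n_complexes = 6, poses_per_complex = 8)
  # graft the toy contact signal into a full-248 schema with all-NA energies
  full <- feature_schema()
  X <- matrix(NA_real_, nrow(ds$X), 248, dimnames = list(NULL, full$columns))
  X[, colnames(ds$X)] <- ds$X
  X[, full$columns[full$block == "property"]] <- 0
  ds_full <- pose_dataset(ds$meta, X, full)
  model <- train_nativeness(ds_full, NULL, list(nrounds = 50), seed = 1)
  prob <- predict_nativeness(model, ds_full)
  expect_true(all(is.finite(prob) & prob >= 0 & prob <= 1))
  expect_gt(pr_auc(ds_full$meta$label, prob), 0.9)
})

test_that("rerank averages children and sorts runs deterministically", {
  mf <- data.frame(
    complex_id = "C1", docking_mode = "default",
    parent_id = rep(c("P1", "P2", "P3"), each = 2),
    refined_id = sprintf("R%d", 1:6), stringsAsFactors = FALSE
  )
  rt <- rerank(c(0.9, 0.9, 0.2, 0.2, 0.6, 0.6), mf)
  expect_equal(rt$parent_id, c("P1", "P3", "P2"))
  expect_equal(rt$rank, 1:3)

  # means 0.60 vs 0.65: the second parent wins despite the higher single child
  mf2 <- mf[1:4, ]; mf2$parent_id <- rep(c("P1", "P2"), each = 2)
  rt2 <- rerank(c(0.8, 0.4, 0.7, 0.6), mf2)
  expect_equal(rt2$parent_id, c("P2", "P1"))
  expect_equal(rt2$mean_prob, c(0.65, 0.60))

  # invariant to within-parent ordering of refined poses
  perm <- c(2, 1, 4, 3, 6, 5)
  rt3 <- rerank(c(0.9, 0.9, 0.2, 0.2, 0.6, 0.6)[perm], mf[perm, ])
  expect_equal(rt3$parent_id, rt$parent_id)

  # single parent ranks first; a listed parent with no children errors
  expect_equal(rerank(0.5, mf[1, ])$rank, 1L)
  expect_error(rerank(0.5, mf[1, ], parents = c("P1", "P9")),
               class = "nbrank_empty_group")

  # ranks are a permutation within each docking run
  mf$docking_mode <- rep(c("default", "antibody"), 3)
  rt4 <- rerank(runif(6), mf)
  for (m in unique(rt4$docking_mode)) {
    expect_setequal(rt4$rank[rt4$docking_mode == m], 1:3)
  }
})

test_that("rank statistics use linear-interpolation quantiles", {
  rt <- function(ranks, labels) {
    data.frame(complex_id = "C", docking_mode = "default",
               parent_id = sprintf("P%d", seq_along(ranks)),
               mean_prob = 0, max_prob = 0, parent_label = labels, rank = ranks)
  }
  expect_equal(rank_statistics(rt(c(1, 1, 1), c(1, 1, 1)))$median, 1)
  expect_equal(rank_statistics(rt(1:5, rep(1, 5)))$median, 3)
  x <- c(2, 5, 1, 9, 4, 7)
  st <- rank_statistics(rt(x, rep(1, 6)))
  s <- sort(x)  # type-7 oracle by direct interpolation
  q_oracle <- function(p) { h <- (6 - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)]) }
  expect_equal(st$median, q_oracle(0.5))
  expect_equal(st$p75, q_oracle(0.75))
  expect_equal(st$p95, q_oracle(0.95))
  expect_true(st$median <= st$p75 && st$p75 <= st$p95)
  expect_error(rank_statistics(rt(1:3, c(0, 0, 0))),
               class = "nbrank_empty_population")
})

test_that("pr_auc matches analytic anchors and the brute-force oracle", {
  expect_equal(pr_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  # constant scores -> prevalence
  expect_equal(pr_auc(c(1, 0, 0, 0), rep(0.5, 4)), 0.25)
  set.seed(5)
  for (i in 1:10) {
    labels <- c(0, 1, sample(0:1, 6, replace = TRUE))
    scores <- round(runif(8), 1)  # ties likely
    expect_equal(pr_auc(labels, scores), brute_pr_auc(labels, scores))
  }
  expect_error(pr_auc(rep(1, 4), runif(4)), class = "nbrank_degenerate_labels")
})

test_that("signed-rank comparison matches exact enumeration", {
  expect_equal(compare_rankings(1:6, 1:6), 1.0)
  set.seed(9)
  for (i in 1:8) {
    a <- sample(1:50, 6); b <- sample(1:50, 6)
    while (any(duplicated(abs(a - b))) || any(a == b)) {
      a <- sample(1:50, 6); b <- sample(1:50, 6)
    }
    expect_equal(compare_rankings(a, b), enumerate_signed_rank_p(a - b))
  }
  # strong domination is detected
  a <- 1:20; b <- a + sample(2:9, 20, replace = TRUE)
  expect_lt(compare_rankings(a, b), 0.05)
  expect_error(compare_rankings(1:4, 1:5), class = "nbrank_pairing_error")
  expect_error(compare_rankings(1:3, 1:3), class = "nbrank_pairing_error")
})

test_that("large-sample signed-rank p agrees with the base-R test", {
  set.seed(33)
  a <- sample(1:100, 40); b <- sample(1:100, 40)
  ours <- compare_rankings(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             exact = FALSE, correct = TRUE))
  expect_equal(ours, ref$p.value, tolerance = 1e-10)
})

test_that("attribution is additive and recovers planted structure", {
  ds <- toy_dataset(n_complexes = 6, poses_per_complex = 8, separation = 5)
  model <- train_nativeness(ds, NULL, list(nrounds = 80), seed = 2)
  att <- attribute(model, ds)
  margins <- predict_nativeness(model, ds, margin = TRUE)
  expect_equal(unname(att$base + rowSums(att$contributions)), margins,
               tolerance = 1e-5)
  # the informative column dominates global importance
  expect_equal(att$importance$feature[1], "n_paratope")

  # single-feature stump: all attribution mass on that feature
  stump <- train_nativeness(ds, NULL,
                            list(nrounds = 10, max_depth = 1, subsample = 1),
                            seed = 3)
  att2 <- attribute(stump, ds)
  others <- setdiff(colnames(att2$contributions), "n_paratope")
  expect_equal(max(abs(att2$contributions[, others])), 0)
  expect_gt(max(abs(att2$contributions[, "n_paratope"])), 0)
})
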