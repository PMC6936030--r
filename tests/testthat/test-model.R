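small_grid <- function(seed = 1) {
  grid_spec(depth_values = c(2L, 4L), fraction_values = c(0.3, 0.6),
            folds = 3L, n_trees = 50L, seed = seed)
}

test_that("stratified folds are disjoint, exhaustive, and balanced", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      n_pos <- sample(10:60, 1); n_neg <- sample(10:60, 1)
      labels <- sample(c(rep("positive", n_pos), rep("negative", n_neg)))
      k <- sample(3:5, 1)
      fold <- make_stratified_folds(labels, k, seed = rep)
      expect_length(fold, n_pos + n_neg)          # exhaustive
      expect_true(all(fold %in% seq_len(k)))      # partition
      for (cls in c("positive", "negative")) {    # stratified to within 1
        per_fold <- tabulate(fold[labels == cls], k)
        expect_lte(max(per_fold) - min(per_fold), 1L)
      }
    }
  })
})

test_that("grid search evaluates every combination on identical folds", {
  ds <- random_dataset(20, w = 9, seed = 41)
  cv <- grid_search_cv(ds, grid = small_grid(seed = 7))
  expect_equal(nrow(cv$grid_scores), 4L)
  expect_equal(nrow(cv$fold_metrics), 4L * 3L)
  # one shared fold assignment, used by all combinations
  per_combo <- split(cv$fold_metrics$fold, cv$fold_metrics$combo)
  expect_true(all(vapply(per_combo, function(f) identical(sort(f), 1:3), logical(1))))
  expect_length(cv$folds, length(ds))
  expect_true(all(cv$grid_scores$mean_acc >= 0 & cv$grid_scores$mean_acc <= 1))
})

test_that("grid search is deterministic given its seed", {
  ds <- random_dataset(15, w = 9, seed = 4)
  a <- grid_search_cv(ds, grid = small_grid(seed = 11))
  b <- grid_search_cv(ds, grid = small_grid(seed = 11))
  expect_identical(a$grid_scores, b$grid_scores)
  expect_identical(a$best, b$best)
})

test_that("tie-breaking prefers the simpler model", {
  # degenerate single-fraction grids cannot tie on fraction, so check order
  ds <- random_dataset(10, w = 9, seed = 8)
  cv <- grid_search_cv(ds, grid = small_grid(seed = 3))
  gs <- cv$grid_scores
  best_score <- max(gs$mean_acc)
  cands <- gs[gs$mean_acc == best_score, , drop = FALSE]
  cands <- cands[order(cands$max_depth, cands$fraction), , drop = FALSE]
  expect_equal(cv$best$max_depth, cands$max_depth[1])
  expect_equal(cv$best$fraction, cands$fraction[1])
})

test_that("single-class or unlabeled datasets are rejected", {
  frags <- replicate(8, random_fragment(9))
  one_class <- fragment_dataset(frags, label = rep("positive", 8))
  expect_error(grid_search_cv(one_class, grid = small_grid()), "both classes")
  unlabeled <- fragment_dataset(frags)
  expect_error(train_final(unlabeled), "unlabeled")
})

test_that("importances normalize to one and vanish on constant central features", {
  ds <- simulate_dataset(strong_signal_spec(n_positive = 60, n_negative = 60, seed = 2))
  for (seed in c(1L, 77L)) {
    m <- train_final(ds, config = forest_config(n_trees = 80, max_depth = 5,
                                                max_features_fraction = 0.5,
                                                seed = seed))
    expect_equal(sum(m$importance), 1, tolerance = 1e-12)
    expect_true(all(m$importance >= 0))
    # central U occupies 0-based features 30, 31, 32 of a 21-mer
    expect_identical(unname(m$importance[31:33]), c(0, 0, 0))
  }
})

test_that("a single planted signal position dominates the importance profile", {
  spec <- signal_spec(
    window_length = 9, n_positive = 150, n_negative = 150,
    biases = data.frame(position = 2, nt = "G", prob = 0.95), seed = 12)
  ds <- simulate_dataset(spec)
  m <- train_final(ds, config = forest_config(n_trees = 150, max_depth = 4,
                                              max_features_fraction = 0.5, seed = 3))
  # argmax must land in the planted position's 3-feature block (0-based 6..8)
  expect_true(which.max(m$importance) %in% 7:9)
})

test_that("prediction is deterministic, thresholded, and length-checked", {
  ds <- simulate_dataset(strong_signal_spec(n_positive = 50, n_negative = 50, seed = 6))
  m <- train_final(ds, config = forest_config(n_trees = 60, max_depth = 6,
                                              max_features_fraction = 0.5, seed = 1))
  p1 <- predict(m, ds)
  p2 <- predict(m, ds)
  expect_identical(p1$score, p2$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_identical(p1$call, ifelse(p1$score >= 0.5, "positive", "negative"))

  frag31 <- paste(c(rep("A", 15), "U", rep("A", 15)), collapse = "")
  expect_error(predict(m, frag31), "window length 21")
})

test_that("a deep forest memorizes its training data", {
  ds <- simulate_dataset(strong_signal_spec(n_positive = 40, n_negative = 40, seed = 9))
  m <- train_final(ds, config = forest_config(n_trees = 200, max_depth = 6,
                                              max_features_fraction = 0.7, seed = 2))
  ev <- evaluate_model(m, ds)
  expect_gt(ev$acc, 0.95)
  # duplicated positive training fragment scores near 1
  dup <- subset_dataset(ds, which(ds$label == "positive")[1])
  expect_gt(predict(m, dup)$score, 0.8)
})

test_that("a random-guess model has MCC near zero on balanced data", {
  withr::with_seed(55, {
    truth <- rep(c("positive", "negative"), each = 500)
    call <- sample(c("positive", "negative"), 1000, replace = TRUE)
  })
  ev <- eval_result(confusion_counts(truth = truth, call = call))
  expect_lt(abs(ev$mcc), 0.12)
})

test_that("model save/load round-trips predictions and checks the format version", {
  ds <- simulate_dataset(strong_signal_spec(n_positive = 30, n_negative = 30, seed = 18))
  m <- train_final(ds, config = forest_config(n_trees = 40, max_depth = 4,
                                              max_features_fraction = 0.4, seed = 5))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "model.rds")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict(back, ds)$score, predict(m, ds)$score)
  expect_equal(back$encoder, "NCP")
  expect_equal(back$window_length, 21L)

  stale <- m; stale$version <- 99L
  saveRDS(stale, path)
  expect_error(load_model(path), "format version")
  saveRDS(list(a = 1), path)
  expect_error(load_model(path), "not a psiforest model")
})

test_that("training on a strong-signal spec beats training on a null spec", {
  strong <- simulate_dataset(strong_signal_spec(n_positive = 120, n_negative = 120, seed = 3))
  null <- simulate_dataset(signal_spec(n_positive = 120, n_negative = 120, seed = 3))
  test_strong <- simulate_dataset(strong_signal_spec(n_positive = 100, n_negative = 100, seed = 91))
  test_null <- simulate_dataset(signal_spec(n_positive = 100, n_negative = 100, seed = 91))
  cfg <- forest_config(n_trees = 100, max_depth = 6, max_features_fraction = 0.5, seed = 1)
  acc_strong <- evaluate_model(train_final(strong, config = cfg), test_strong)$acc
  acc_null <- evaluate_model(train_final(null, config = cfg), test_null)$acc
  expect_gt(acc_strong, acc_null + 0.15)
})

test_that("the CV heatmap TSV mirrors the grid shape", {
  ds <- random_dataset(12, w = 9, seed = 62)
  cv <- grid_search_cv(ds, grid = small_grid(seed = 2))
  path <- file.path(withr::local_tempdir(), "heatmap.tsv")
  write_cv_heatmap(cv, path)
  hm <- read.delim(path, check.names = FALSE)
  expect_equal(dim(hm), c(2L, 3L))  # 2 depths x (label col + 2 fractions)
  expect_equal(hm$max_depth, c(2L, 4L))
})
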