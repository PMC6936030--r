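# Random-forest training: exhaustive (depth x feature-fraction) grid
# search under stratified k-fold cross-validation, final refit,
# impurity-based importance profiling, vote-fraction prediction.

MODEL_FORMAT_VERSION <- 1L
CLASS_LEVELS <- c("negative", "positive")

#' Random-forest configuration
#'
#' @param n_trees trees per forest (default 200).
#' @param max_depth maximum tree depth.
#' @param max_features_fraction fraction of features considered at each
#'   split, in `(0, 1]`; converted to a per-split feature count as
#'   `round(fraction * n_features)`, minimum 1.
#' @param seed integer seed for the forest.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 200L, max_depth = 6L,
                          max_features_fraction = 0.5, seed = 1L) {
  stopifnot(n_trees >= 1L, max_depth >= 1L,
            max_features_fraction > 0, max_features_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 max_features_fraction = max_features_fraction,
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Hyper-parameter grid for cross-validated tuning
#'
#' Defaults follow the published search: depth 2–6 crossed with
#' per-split feature fractions 20% to 80% in 5% steps (65
#' combinations), 200 trees, 5 folds.
#'
#' @param depth_values integer vector of `max_depth` candidates.
#' @param fraction_values numeric vector of feature-fraction candidates.
#' @param folds number of CV folds (>= 2).
#' @param n_trees trees per forest.
#' @param seed seed for fold assignment and all forest fits.
#' @param criterion model-selection score: mean fold `"accuracy"`
#'   (default) or `"mcc"`.
#' @param aggregation `"mean"` over folds (default) or `"pooled"` over
#'   concatenated fold predictions.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(depth_values = 2:6,
                      fraction_values = seq(0.20, 0.80, by = 0.05),
                      folds = 5L, n_trees = 200L, seed = 1L,
                      criterion = c("accuracy", "mcc"),
                      aggregation = c("mean", "pooled")) {
  stopifnot(length(depth_values) >= 1L, length(fraction_values) >= 1L, folds >= 2L)
  structure(list(depth_values = as.integer(depth_values),
                 fraction_values = fraction_values,
                 folds = as.integer(folds), n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 criterion = match.arg(criterion),
                 aggregation = match.arg(aggregation)),
            class = "grid_spec")
}

#' Stratified fold assignment
#'
#' Folds are disjoint, exhaustive, and stratified: within each class,
#' per-fold counts differ by at most one.
#'
#' @param labels character vector over `{"positive","negative"}`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector in `1..k`, one entry per sample.
#' @export
make_stratified_folds <- function(labels, k, seed = 1L) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

dataset_labels <- function(dataset) {
  lab <- dataset$label
  if (anyNA(lab)) stop("dataset contains unlabeled fragments; a labeled dataset is required")
  if (length(unique(lab)) < 2L) stop("training requires both classes present")
  factor(lab, levels = CLASS_LEVELS)
}

fit_forest <- function(x, y, n_trees, max_depth, fraction, seed, importance = "none") {
  mtry <- max(1L, round(fraction * ncol(x)))
  ranger::ranger(x = x, y = y, num.trees = n_trees, mtry = mtry,
                 max.depth = max_depth, importance = importance,
                 seed = seed, num.threads = 1L, classification = TRUE)
}

# Fraction of trees voting "positive", per row of x. Per-tree codes
# index directly into forest$levels.
vote_scores <- function(fit, x) {
  codes <- predict(fit, data = x, predict.all = TRUE, num.threads = 1L)$predictions
  pos_code <- which(fit$forest$levels == "positive")
  rowMeans(matrix(codes == pos_code, nrow = nrow(codes)))
}

#' Exhaustive grid search under stratified k-fold cross-validation
#'
#' Every (depth, fraction) combination is evaluated on the *same* fold
#' split (a paired comparison). All encoders are label-free functions
#' of the fragment, so encoding once up front cannot leak fold labels.
#' The best combination maximizes the mean fold score; ties break
#' toward the smaller depth, then the smaller fraction (the simpler
#' model).
#'
#' @param dataset a labeled `fragment_dataset` with both classes.
#' @param encoder,encoder_params passed to [encode_dataset()].
#' @param grid a [grid_spec()].
#' @return an object of class `psi_cv`: `grid_scores` (one row per
#'   combination with the mean fold metrics), `fold_metrics` (one row
#'   per combination x fold), `best` (depth, fraction, score), `folds`
#'   (the shared assignment), and the grid settings used.
#' @export
grid_search_cv <- function(dataset, encoder = "NCP", encoder_params = list(),
                           grid = grid_spec()) {
  y <- dataset_labels(dataset)
  x <- do.call(encode_dataset, c(list(dataset, encoder), encoder_params))
  x <- unclass_features(x)
  folds <- make_stratified_folds(as.character(y), grid$folds, grid$seed)
  combos <- expand.grid(max_depth = grid$depth_values,
                        fraction = grid$fraction_values,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$max_depth, combos$fraction), , drop = FALSE]
  rownames(combos) <- NULL
  fit_seeds <- withr::with_seed(grid$seed,
    matrix(sample.int(.Machine$integer.max, nrow(combos) * grid$folds),
           nrow = nrow(combos)))
  fold_rows <- list()
  for (ci in seq_len(nrow(combos))) {
    for (f in seq_len(grid$folds)) {
      tr <- folds != f
      fit <- fit_forest(x[tr, , drop = FALSE], y[tr], grid$n_trees,
                        combos$max_depth[ci], combos$fraction[ci],
                        fit_seeds[ci, f])
      sc <- vote_scores(fit, x[!tr, , drop = FALSE])
      call <- ifelse(sc >= 0.5, "positive", "negative")
      cc <- confusion_counts(truth = as.character(y[!tr]), call = call)
      ev <- suppressWarnings(eval_result(cc))
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        combo = ci, max_depth = combos$max_depth[ci],
        fraction = combos$fraction[ci], fold = f,
        tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
        sn = ev$sn, sp = ev$sp, acc = ev$acc, mcc = ev$mcc)
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  grid_scores <- do.call(rbind, lapply(seq_len(nrow(combos)), function(ci) {
    fm <- fold_metrics[fold_metrics$combo == ci, , drop = FALSE]
    pooled <- suppressWarnings(eval_result(confusion_counts(
      tp = sum(fm$tp), fp = sum(fm$fp), tn = sum(fm$tn), fn = sum(fm$fn))))
    data.frame(max_depth = combos$max_depth[ci], fraction = combos$fraction[ci],
               mean_acc = mean(fm$acc), mean_sn = mean(fm$sn),
               mean_sp = mean(fm$sp), mean_mcc = mean(fm$mcc),
               pooled_acc = pooled$acc, pooled_mcc = pooled$mcc)
  }))
  score <- switch(paste(grid$aggregation, grid$criterion),
                  "mean accuracy" = grid_scores$mean_acc,
                  "mean mcc" = grid_scores$mean_mcc,
                  "pooled accuracy" = grid_scores$pooled_acc,
                  "pooled mcc" = grid_scores$pooled_mcc)
  ord <- order(-score, grid_scores$max_depth, grid_scores$fraction)
  best_i <- ord[1]
  structure(list(
    grid_scores = grid_scores, fold_metrics = fold_metrics,
    best = list(max_depth = grid_scores$max_depth[best_i],
                fraction = grid_scores$fraction[best_i],
                score = score[best_i]),
    folds = folds, grid = grid, encoder = encoder,
    encoder_params = encoder_params),
    class = "psi_cv")
}

unclass_features <- function(x) {
  m <- unclass(x)
  attr(m, "encoder_id") <- NULL; attr(m, "encoder_params") <- NULL
  attr(m, "label") <- NULL; attr(m, "window_length") <- NULL
  m
}

#' @export
print.psi_cv <- function(x, ...) {
  cat(sprintf("psi_cv: %d combinations x %d folds (%s %s)\n",
              nrow(x$grid_scores), x$grid$folds, x$grid$aggregation,
              x$grid$criterion))
  cat(sprintf("  best: max_depth=%d  fraction=%.2f  score=%.4f\n",
              x$best$max_depth, x$best$fraction, x$best$score))
  invisible(x)
}

#' Export the CV accuracy grid as a heatmap-shaped TSV
#'
#' Rows are depth values, columns feature fractions, cells the mean
#' fold accuracy.
#'
#' @param cv a `psi_cv`.
#' @param path output TSV path.
#' @export
write_cv_heatmap <- function(cv, path) {
  gs <- cv$grid_scores
  depths <- sort(unique(gs$max_depth))
  fracs <- sort(unique(gs$fraction))
  m <- matrix(NA_real_, length(depths), length(fracs),
              dimnames = list(depths, sprintf("%.2f", fracs)))
  for (i in seq_len(nrow(gs))) {
    m[as.character(gs$max_depth[i]), sprintf("%.2f", gs$fraction[i])] <- gs$mean_acc[i]
  }
  df <- data.frame(max_depth = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Train a final forest on the full dataset
#'
#' Fits a forest with the given configuration on every labeled sample
#' and profiles impurity-based feature importances, normalized to sum
#' to one. Features that are constant across the dataset — such as the
#' three NCP flags of the always-U central position — receive exactly
#' zero importance for any seed.
#'
#' @param dataset a labeled `fragment_dataset`.
#' @param encoder,encoder_params passed to [encode_dataset()].
#' @param config a [forest_config()] (typically built from
#'   `psi_cv$best`).
#' @return an object of class `psi_model`.
#' @export
train_final <- function(dataset, encoder = "NCP", encoder_params = list(),
                        config = forest_config()) {
  y <- dataset_labels(dataset)
  x <- do.call(encode_dataset, c(list(dataset, encoder), encoder_params))
  x <- unclass_features(x)
  fit <- fit_forest(x, y, config$n_trees, config$max_depth,
                    config$max_features_fraction, config$seed,
                    importance = "impurity")
  imp <- fit$variable.importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(fit = fit, config = config, encoder = encoder,
                 encoder_params = encoder_params,
                 feature_names = colnames(x),
                 importance = imp,
                 window_length = dataset$window_length,
                 species_tag = dataset$species_tag,
                 version = MODEL_FORMAT_VERSION),
            class = "psi_model")
}

#' @export
print.psi_model <- function(x, ...) {
  cat(sprintf("psi_model: %s encoder, window %d, %d trees, depth %d, fraction %.2f (species %s)\n",
              x$encoder, x$window_length, x$config$n_trees,
              x$config$max_depth, x$config$max_features_fraction, x$species_tag))
  invisible(x)
}

#' Predict pseudouridine scores for fragments
#'
#' The score of a fragment is the fraction of trees voting positive; a
#' fragment is called positive when the score reaches `threshold`
#' (default 0.5). Deterministic for a fitted model.
#'
#' @param object a `psi_model`.
#' @param fragments a `fragment_dataset` or character vector of
#'   fragments matching the model's window length.
#' @param threshold vote-fraction calling threshold.
#' @param ... unused.
#' @return data.frame with `id`, `score`, `call`.
#' @export
predict.psi_model <- function(object, fragments, threshold = 0.5, ...) {
  if (is.character(fragments)) fragments <- fragment_dataset(fragments)
  if (length(fragments) == 0L) {
    return(data.frame(id = character(0), score = numeric(0), call = character(0)))
  }
  if (fragments$window_length != object$window_length) {
    stop("fragment length ", fragments$window_length,
         " does not match the model's expected window length ",
         object$window_length)
  }
  x <- do.call(encode_dataset,
               c(list(fragments, object$encoder), object$encoder_params))
  x <- unclass_features(x)
  sc <- vote_scores(object$fit, x)
  data.frame(id = fragments$id, score = sc,
             call = ifelse(sc >= threshold, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Evaluate a model on a labeled test set
#'
#' @param model a `psi_model`.
#' @param test a labeled `fragment_dataset` with matching window
#'   length.
#' @param threshold calling threshold passed to [predict.psi_model()].
#' @return a `psi_eval`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  lab <- test$label
  if (anyNA(lab)) stop("test dataset contains unlabeled fragments")
  pred <- predict(model, test, threshold = threshold)
  eval_result(confusion_counts(truth = lab, call = pred$call))
}

#' Save / load a trained model
#'
#' The single-file bundle embeds the fitted forest, the encoder spec,
#' the window length, the species tag, and a format version; loading a
#' file with a different format version fails loudly. A round-trip
#' reproduces predictions exactly.
#'
#' @param model a `psi_model`.
#' @param path model file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psi_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file '", path,
                                           "': ", conditionMessage(e)))
  if (!inherits(obj, "psi_model") || is.null(obj$version)) {
    stop("'", path, "' is not a psiforest model file")
  }
  if (obj$version != MODEL_FORMAT_VERSION) {
    stop("model format version ", obj$version,
         " not supported (expected ", MODEL_FORMAT_VERSION, ")")
  }
  obj
}
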