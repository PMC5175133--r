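#' Random-forest parameters
#'
#' @param n_trees Number of trees; default 100.
#' @param max_features Features tried per split; default `floor(sqrt(d))`,
#'   resolved at fit time when `NULL`.
#' @param seed Integer seed.
#' @return List of class `rf_params`.
#' @export
rf_params <- function(n_trees = 100, max_features = NULL, seed = 1) {
  stopifnot(is_count1(n_trees), n_trees >= 1)
  structure(list(n_trees = n_trees, max_features = max_features, seed = seed),
            class = "rf_params")
}

#' Train a random-forest classifier
#'
#' Fits an ensemble of decision trees on bootstrap resamples with random
#' feature subsets at each split; prediction is the majority vote and the
#' score is the positive-class vote fraction. Tree induction is delegated to
#' the `randomForest` package.
#'
#' @param X Numeric feature matrix (rows = instances).
#' @param y Class labels (2 levels, each with at least 1 row).
#' @param params An [rf_params()].
#' @param positive Label treated as the positive class for scoring; default
#'   first factor level.
#' @return Object of class `profam_rf`.
#' @export
train_rf <- function(X, y, params = rf_params(), positive = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) data_error("training labels contain a single class")
  stopifnot(nrow(X) >= 2L, nrow(X) == length(y))
  if (is.null(positive)) positive <- levels(y)[1]
  ## degenerate design: no feature varies, so no split is possible; fall
  ## back to a prior model whose score is the training class frequency
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    return(structure(list(forest = NULL, levels = levels(y), positive = positive,
                          prior = mean(y == positive),
                          majority = names(which.max(table(y))),
                          params = params, features = colnames(X)),
                     class = "profam_rf"))
  }
  mtry <- if (is.null(params$max_features)) max(1L, floor(sqrt(ncol(X)))) else params$max_features
  fit <- with_rng_seed(params$seed,
    randomForest::randomForest(x = X, y = y, ntree = params$n_trees, mtry = mtry))
  structure(list(forest = fit, levels = levels(y), positive = positive,
                 params = params, features = colnames(X)),
            class = "profam_rf")
}

#' Predict classes or vote-fraction scores from a trained forest
#'
#' @param object A `profam_rf` model.
#' @param newdata Numeric feature matrix.
#' @param type `"class"` (majority vote) or `"score"` (positive-class vote
#'   fraction in `[0, 1]`).
#' @param ... Unused.
#' @return Character vector of classes or numeric vector of scores.
#' @export
predict.profam_rf <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(object$forest)) {
    return(if (type == "class") rep(object$majority, nrow(newdata))
           else rep(object$prior, nrow(newdata)))
  }
  if (type == "class")
    as.character(stats::predict(object$forest, newdata, type = "response"))
  else
    as.numeric(stats::predict(object$forest, newdata, type = "prob")[, object$positive])
}

## Stratified fold ids: within each class, shuffled round-robin assignment,
## so fold sizes per class differ by at most 1.
stratified_folds <- function(y, folds, seed) {
  with_rng_seed(seed, {
    id <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds)
        data_error("class '%s' has %d members, fewer than %d folds",
                   cl, length(idx), folds)
      id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
}

#' Stratified k-fold cross-validation of the random forest
#'
#' Folds are stratified by class. Two protocols are offered:
#' * `"within-fold"` (default, methodologically sound): SMOTE, when
#'   configured, is applied to the training split of each fold only; held-out
#'   instances are never used to synthesize training points.
#' * `"paper-mode"`: the full dataset is oversampled first and folds are then
#'   drawn from the augmented data. This replicates the common workbench
#'   workflow of filtering before cross-validating and is optimistic, since
#'   synthetic points derived from test instances can appear in training.
#'
#' @param X Numeric feature matrix.
#' @param y Class labels (2 classes).
#' @param folds Number of folds; default 10.
#' @param smote A [smote_config()] or `NULL` to disable oversampling.
#' @param mode `"within-fold"` or `"paper-mode"`.
#' @param params An [rf_params()].
#' @param positive Positive-class label; default the minority class.
#' @param seed Seed for fold assignment (per-fold forests derive their seeds
#'   from it).
#' @return Object of class `cv_result`: pooled `confusion` matrix, `metrics`
#'   (fractions), `auc`, `per_fold` data frame, and `scores` data frame of
#'   out-of-fold positive-class scores (each original instance scored exactly
#'   once).
#' @export
crossvalidate <- function(X, y, folds = 10, smote = NULL,
                          mode = c("within-fold", "paper-mode"),
                          params = rf_params(), positive = NULL, seed = 1) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), folds >= 2)
  if (length(unique(y)) != 2L) data_error("exactly two classes required")
  if (is.null(positive)) {
    cnt <- table(factor(y, levels = unique(y)))
    positive <- names(cnt)[which.min(cnt)]
  }
  negative <- setdiff(unique(y), positive)
  if (!is.null(smote) && mode == "paper-mode") {
    reb <- rebalance_dataset(X, y, smote, minority_label = positive)
    X <- reb$X; y <- reb$y
  }
  fold_id <- if (folds == length(y)) seq_along(y)   # leave-one-out
             else stratified_folds(y, folds, seed)
  score <- rep(NA_real_, length(y))
  pred <- rep(NA_character_, length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    if (!is.null(smote) && mode == "within-fold") {
      cfg <- smote; cfg$seed <- smote$seed + f
      reb <- rebalance_dataset(Xtr, ytr, cfg, minority_label = positive)
      Xtr <- reb$X; ytr <- reb$y
    }
    p <- params; p$seed <- params$seed + f
    mdl <- train_rf(Xtr, ytr, p, positive = positive)
    score[te] <- predict(mdl, X[te, , drop = FALSE], type = "score")
    pred[te] <- predict(mdl, X[te, , drop = FALSE], type = "class")
    cmf <- confusion_matrix(tp = sum(y[te] == positive & pred[te] == positive),
                            fn = sum(y[te] == positive & pred[te] != positive),
                            fp = sum(y[te] == negative & pred[te] == positive),
                            tn = sum(y[te] == negative & pred[te] != positive))
    safe <- function(fun) tryCatch(fun(cmf), error = function(e) NA_real_)
    per_fold[[f]] <- data.frame(fold = f, Sn = safe(sensitivity), Sp = safe(specificity),
                                Acc = safe(accuracy), MCC = safe(mcc))
  }
  cm <- confusion_matrix(tp = sum(y == positive & pred == positive),
                         fn = sum(y == positive & pred != positive),
                         fp = sum(y == negative & pred == positive),
                         tn = sum(y == negative & pred != positive))
  structure(list(confusion = cm,
                 metrics = metrics_summary(cm)$fraction,
                 auc = roc_auc(score, y, positive = positive),
                 per_fold = do.call(rbind, per_fold),
                 scores = data.frame(truth = y, fold = fold_id, score = score,
                                     stringsAsFactors = FALSE),
                 positive = positive, mode = mode, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s), positive class '%s'\n",
              x$folds, x$mode, x$positive))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f  AUC %.4f\n",
              m[["Sn"]], m[["Sp"]], m[["Acc"]], m[["MCC"]], x$auc))
  invisible(x)
}
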