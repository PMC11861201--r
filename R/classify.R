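# Random-forest facial-expression classification from sliding-window
# features, with the pooled 10/2 reordered-trial split and the standard
# metric suite (accuracy, precision/recall/F1, one-vs-rest ROC/AUC,
# confusion matrix).

#' Split reordered trials into pooled train and test sets
#'
#' Per participant, draws a random permutation of `n_train` of the
#' reordered trials for training; the remainder are the test set. Pools
#' across participants.
#'
#' @param trials_by_participant List (one element per participant) of
#'   lists of reordered trials (any payload; commonly feature tables).
#' @param n_train Trials per participant used for training (default 10).
#' @param seed Integer seed; the split is deterministic given it.
#' @return List with `train`, `test` (flat lists of payloads) and
#'   `assignment` (data.frame: participant, trial, role).
#' @export
split_train_test <- function(trials_by_participant, n_train = 10L, seed = 1L) {
  n_trials <- length(trials_by_participant[[1L]])
  if (n_train >= n_trials)
    stop("n_train must be smaller than the number of trials (", n_trials, ")")
  train <- list(); test <- list(); rows <- list()
  for (p in seq_along(trials_by_participant)) {
    tr <- trials_by_participant[[p]]
    if (length(tr) != n_trials) stop("participant ", p, " has ", length(tr),
                                     " trials; expected ", n_trials)
    idx <- with_seed(derive_seed(seed, 202L, p), sample.int(n_trials))
    take <- idx[seq_len(n_train)]
    train <- c(train, tr[take])
    test <- c(test, tr[setdiff(idx, take)])
    rows[[p]] <- data.frame(participant = p, trial = idx,
                            role = rep(c("train", "test"),
                                       c(n_train, n_trials - n_train)))
  }
  list(train = train, test = test, assignment = do.call(rbind, rows))
}

bind_feature_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Train a random-forest expression classifier
#'
#' Fits a 100-tree probability random forest on the feature columns of a
#' feature table and reports 5-fold cross-validated accuracy on the
#' training rows; the final model is fit on all rows.
#'
#' @param features A `feature_table` (or data.frame) with a `label`
#'   column and feature columns.
#' @param n_trees Number of trees (default 100).
#' @param cv_folds Cross-validation folds for the reported training
#'   accuracy (default 5; 0 skips CV).
#' @param seed Integer seed for the forest and the fold assignment.
#' @return Object of class `fer_classifier`: the ranger model, the
#'   feature-column names, class levels and `cv_accuracy`.
#' @export
train_classifier <- function(features, n_trees = 100L, cv_folds = 5L, seed = 1L) {
  df <- as.data.frame(features)
  feat_cols <- setdiff(names(df), c("t_center_s", "label"))
  y <- factor(df$label)
  if (nlevels(droplevels(y)) < 2L) stop("training data contains a single class")
  x <- df[, feat_cols, drop = FALSE]
  fit_forest <- function(xx, yy, s) {
    ranger::ranger(x = xx, y = yy, num.trees = n_trees, probability = TRUE,
                   seed = s, num.threads = 1L)
  }
  cv_accuracy <- NA_real_
  if (cv_folds > 1L) {
    folds <- with_seed(derive_seed(seed, 303L),
                       sample(rep_len(seq_len(cv_folds), nrow(df))))
    hits <- 0L
    for (f in seq_len(cv_folds)) {
      m <- fit_forest(x[folds != f, , drop = FALSE], droplevels(y[folds != f]),
                      derive_seed(seed, 304L, f))
      pr <- stats::predict(m, data = x[folds == f, , drop = FALSE])$predictions
      pred <- colnames(pr)[max.col(pr, ties.method = "first")]
      hits <- hits + sum(pred == as.character(y[folds == f]))
    }
    cv_accuracy <- 100 * hits / nrow(df)
  }
  model <- fit_forest(x, y, derive_seed(seed, 305L))
  structure(list(model = model, feature_names = feat_cols,
                 classes = levels(y), n_trees = n_trees,
                 cv_accuracy = cv_accuracy),
            class = "fer_classifier")
}

#' @export
print.fer_classifier <- function(x, ...) {
  cat(sprintf("<fer_classifier> random forest, %d trees, %d features, %d classes\n",
              x$n_trees, length(x$feature_names), length(x$classes)))
  if (!is.na(x$cv_accuracy))
    cat(sprintf("  training CV accuracy: %.2f%%\n", x$cv_accuracy))
  invisible(x)
}

#' Evaluate an expression classifier on held-out windows
#'
#' Window-wise test metrics: overall and per-class accuracy, precision,
#' recall, F1, one-vs-rest ROC curves with AUC (from the forest's class
#' probabilities) and the confusion matrix (true labels in rows,
#' predictions in columns).
#'
#' @param clf A `fer_classifier`.
#' @param test A feature table with the same feature schema.
#' @return Object of class `classifier_report`.
#' @export
evaluate_classifier <- function(clf, test) {
  df <- as.data.frame(test)
  if (!all(clf$feature_names %in% names(df)))
    stop("test features do not match the training schema")
  x <- df[, clf$feature_names, drop = FALSE]
  truth <- factor(df$label, levels = clf$classes)
  prob <- stats::predict(clf$model, data = x)$predictions
  pred <- factor(colnames(prob)[max.col(prob, ties.method = "first")],
                 levels = clf$classes)
  cm <- table(true = truth, predicted = pred)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  per_class <- lapply(clf$classes, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else NA_real_
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    auc <- NA_real_; roc <- NULL
    if (cl %in% truth && any(truth != cl)) {
      roc <- pROC::roc(response = as.integer(truth == cl),
                       predictor = prob[, cl], quiet = TRUE,
                       direction = "<", levels = c(0L, 1L))
      auc <- as.numeric(pROC::auc(roc))
    }
    list(accuracy = 100 * rec, precision = prec, recall = rec, f1 = f1,
         auc = auc, roc = roc)
  })
  names(per_class) <- clf$classes
  structure(list(accuracy = acc,
                 per_class = per_class,
                 confusion = cm,
                 n_windows = nrow(df)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d test windows, accuracy %.2f%%\n",
              x$n_windows, x$accuracy))
  tab <- do.call(rbind, lapply(x$per_class, function(p)
    c(accuracy = p$accuracy, precision = p$precision, recall = p$recall,
      f1 = p$f1, auc = p$auc)))
  print(round(tab, 4))
  invisible(x)
}
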