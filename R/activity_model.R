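#' Train the random-forest activity recogniser
#'
#' Standardizes the training features (parameters estimated on these
#' windows only) and fits a seeded random forest over the seven
#' daily-activity classes. Defaults: 100 trees, unlimited depth,
#' `floor(sqrt(561)) = 23` candidate features per split — the
#' library-standard baseline, recorded in the model metadata.
#'
#' @param features numeric matrix, one 561-element feature vector per row.
#' @param labels activity label per row (subset of [ACTIVITY_LABELS]).
#' @param num_trees number of trees (default 100).
#' @param mtry candidate features per split (default `floor(sqrt(p))`).
#' @param seed RNG seed controlling the forest (default 42); the same data
#'   and seed reproduce identical predictions.
#' @return A `belt_model`: list with the fitted forest, the frozen
#'   `belt_standardizer`, `feature_names`, `classes` and `meta`.
#' @export
train_activity_model <- function(features, labels, num_trees = 100,
                                 mtry = NULL, seed = 42) {
  features <- check_feature_matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop_belt("one label per feature row required")
  }
  unknown <- setdiff(unique(labels), ACTIVITY_LABELS)
  if (length(unknown)) {
    stop_belt(sprintf("unknown activity label(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  if (length(unique(labels)) < 2) {
    stop_belt("training data must contain at least 2 classes")
  }
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(features)))
  std <- fit_standardizer(features)
  xs <- apply_standardizer(std, features)
  y <- factor(labels, levels = ACTIVITY_LABELS)
  y <- droplevels(y)
  forest <- ranger::ranger(
    x = xs, y = y,
    num.trees = num_trees, mtry = mtry,
    num.threads = 1, seed = as.integer(seed)
  )
  structure(
    list(forest = forest, standardizer = std,
         feature_names = colnames(features), classes = levels(y),
         meta = list(num_trees = num_trees, mtry = mtry, seed = seed,
                     n_train = nrow(features))),
    class = "belt_model"
  )
}

check_feature_matrix <- function(features) {
  features <- as.matrix(features)
  if (ncol(features) != 561) {
    stop_belt(sprintf("feature vectors must have length 561, got %d",
                      ncol(features)))
  }
  if (is.null(colnames(features))) colnames(features) <- feature_names()
  features
}

#' @export
print.belt_model <- function(x, ...) {
  cat(sprintf(
    "<belt_model> random forest: %d trees, mtry %d, %d classes, %d training windows\n",
    x$meta$num_trees, x$meta$mtry, length(x$classes), x$meta$n_train))
  invisible(x)
}

#' Predict activity labels for feature windows
#'
#' @param model a `belt_model` from [train_activity_model()].
#' @param features numeric matrix of 561-element feature vectors.
#' @return Factor of predicted labels (levels = the model's classes);
#'   empty input gives an empty factor.
#' @export
predict_activity <- function(model, features) {
  if (!inherits(model, "belt_model")) stop_belt("model must be a belt_model")
  features <- check_feature_matrix(features)
  if (nrow(features) == 0) {
    return(factor(character(0), levels = model$classes))
  }
  xs <- apply_standardizer(model$standardizer, features)
  stats::predict(model$forest, data = xs, num.threads = 1)$predictions
}

#' Confusion matrix and F1 scores
#'
#' `confusion_matrix()` tabulates true x predicted counts over a fixed
#' label set; `f1_scores()` derives per-class precision, recall and F1 plus
#' macro (unweighted class mean) and weighted (support-weighted) averages.
#' Classes with no predicted and no true instances contribute
#' precision = recall = F1 = 0.
#'
#' @param truth,predicted label vectors of equal length.
#' @param classes label set fixing row/column order (default: the labels
#'   present).
#' @return `confusion_matrix()`: integer matrix (rows = truth);
#'   `f1_scores()`: list with `per_class` data frame, `f1_macro`,
#'   `f1_weighted`, `accuracy`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (length(truth) != length(predicted)) {
    stop_belt("truth and predicted must have equal length")
  }
  if (is.null(classes)) classes <- sort(unique(c(as.character(truth),
                                                 as.character(predicted))))
  table(
    truth = factor(as.character(truth), levels = classes),
    predicted = factor(as.character(predicted), levels = classes)
  )
}

#' @rdname confusion_matrix
#' @param cm a confusion matrix from `confusion_matrix()`.
#' @export
f1_scores <- function(cm) {
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- support > 0
  list(
    per_class = data.frame(
      class = rownames(cm), support = as.integer(support),
      precision = as.numeric(precision), recall = as.numeric(recall),
      f1 = as.numeric(f1), row.names = NULL
    ),
    f1_macro = mean(f1[present]),
    f1_weighted = sum(f1[present] * support[present]) / sum(support),
    accuracy = sum(tp) / sum(cm)
  )
}

#' Stratified k-fold cross-validation of the activity recogniser
#'
#' Shuffles windows (seeded), assigns them to `k` folds stratified so every
#' fold covers the classes in the same ratio (per-class fold sizes differ
#' by at most one), and per fold standardizes on the training windows, fits
#' the forest and predicts the held-out windows. Standardization and model
#' fitting never see test-fold data. Predictions are pooled into one
#' confusion matrix.
#'
#' @param features numeric matrix of 561-element feature vectors.
#' @param labels activity labels, one per row; every class needs at least
#'   `k` windows.
#' @param k number of folds (default 10).
#' @param seed RNG seed for fold assignment and forests (default 42).
#' @param num_trees,mtry forest hyperparameters, see
#'   [train_activity_model()].
#' @return A `belt_eval`: list with `confusion`, `per_class`, `f1_macro`,
#'   `f1_weighted`, `accuracy`, `folds` (fold id per window), `scheme`.
#' @export
evaluate_kfold <- function(features, labels, k = 10, seed = 42,
                           num_trees = 100, mtry = NULL) {
  features <- check_feature_matrix(features)
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < k)) {
    lacking <- names(counts)[counts < k]
    stop_belt(sprintf("stratification impossible: class(es) %s have fewer than k = %d windows",
                      paste(lacking, collapse = ", "), k))
  }
  folds <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  run_folds(features, labels, folds, scheme = "kfold", seed = seed,
            num_trees = num_trees, mtry = mtry)
}

#' Leave-one-person-out cross-validation
#'
#' One fold per subject: each subject's windows are held out in turn while
#' the remaining subjects train the model, measuring cross-subject
#' generalisation. Reports the pooled confusion matrix plus a per-subject
#' F1 table; `group_by` (a named vector mapping subject id to a group tag,
#' e.g. gender) adds pooled per-group reports.
#'
#' @param features numeric matrix of 561-element feature vectors.
#' @param labels activity labels, one per row.
#' @param subjects subject identifier per row; at least 2 distinct.
#' @param group_by optional named vector: `group_by[subject id] = group`.
#' @param seed,num_trees,mtry see [evaluate_kfold()].
#' @return A `belt_eval` with the additional elements `per_subject` (data
#'   frame of per-subject weighted F1) and, when `group_by` is given,
#'   `per_group` (named list of pooled `belt_eval`s).
#' @export
evaluate_lopo <- function(features, labels, subjects, group_by = NULL,
                          seed = 42, num_trees = 100, mtry = NULL) {
  features <- check_feature_matrix(features)
  labels <- as.character(labels)
  if (length(subjects) != nrow(features) || anyNA(subjects)) {
    stop_belt("a non-missing subject id is required for every window")
  }
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  if (length(ids) < 2) stop_belt("leave-one-person-out needs at least 2 subjects")
  folds <- match(subjects, ids)
  res <- run_folds(features, labels, folds, scheme = "lopo", seed = seed,
                   num_trees = num_trees, mtry = mtry)
  classes <- rownames(res$confusion)
  res$per_subject <- data.frame(
    subject = ids,
    f1_weighted = vapply(seq_along(ids), function(i) {
      sel <- folds == i
      f1_scores(confusion_matrix(labels[sel], res$predictions[sel],
                                 classes))$f1_weighted
    }, numeric(1)),
    row.names = NULL
  )
  if (!is.null(group_by)) {
    res$per_group <- lapply(split(ids, group_by[ids]), function(members) {
      sel <- subjects %in% members
      cm <- confusion_matrix(labels[sel], res$predictions[sel], classes)
      c(list(confusion = cm), f1_scores(cm))
    })
  }
  res
}

run_folds <- function(features, labels, folds, scheme, seed, num_trees,
                      mtry) {
  classes <- ACTIVITY_LABELS[ACTIVITY_LABELS %in% unique(labels)]
  predictions <- character(length(labels))
  for (f in sort(unique(folds))) {
    test <- folds == f
    model <- train_activity_model(
      features[!test, , drop = FALSE], labels[!test],
      num_trees = num_trees, mtry = mtry, seed = seed + f
    )
    predictions[test] <- as.character(
      predict_activity(model, features[test, , drop = FALSE]))
  }
  cm <- confusion_matrix(labels, predictions, classes)
  structure(
    c(list(confusion = cm), f1_scores(cm),
      list(folds = folds, predictions = predictions, scheme = scheme,
           seed = seed)),
    class = "belt_eval"
  )
}

#' @export
print.belt_eval <- function(x, ...) {
  cat(sprintf("<belt_eval> %s: %d windows, %d folds\n", x$scheme,
              sum(x$confusion), length(unique(x$folds))))
  cat(sprintf("  F1 weighted %.3f | F1 macro %.3f | accuracy %.3f\n",
              x$f1_weighted, x$f1_macro, x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the scores and per-class table as JSON and the pooled confusion
#' matrix as CSV (`<stem>.json`, `<stem>_confusion.csv`).
#'
#' @param eval_report a `belt_eval`.
#' @param stem output path stem (without extension).
#' @return The JSON path, invisibly.
#' @export
write_eval_report <- function(eval_report, stem) {
  json_path <- paste0(stem, ".json")
  payload <- list(
    schema_version = "1.0",
    scheme = eval_report$scheme,
    f1_weighted = eval_report$f1_weighted,
    f1_macro = eval_report$f1_macro,
    accuracy = eval_report$accuracy,
    per_class = eval_report$per_class
  )
  if (!is.null(eval_report$per_subject)) {
    payload$per_subject <- eval_report$per_subject
  }
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame.matrix(eval_report$confusion),
            paste0(stem, "_confusion.csv"))
  invisible(json_path)
}
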