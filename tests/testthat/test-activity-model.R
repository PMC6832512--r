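test_that("training on separable classes reaches perfect training accuracy, deterministically", {
  fx <- separable_features()
  model <- train_activity_model(fx$features, fx$labels, seed = 1)
  pred <- predict_activity(model, fx$features)
  expect_equal(mean(as.character(pred) == fx$labels), 1.0)

  # same data + same seed -> identical predictions
  model2 <- train_activity_model(fx$features, fx$labels, seed = 1)
  expect_identical(as.character(predict_activity(model2, fx$features)),
                   as.character(pred))

  expect_error(train_activity_model(fx$features[, 1:100], fx$labels), "561")
  expect_error(train_activity_model(fx$features, rep("sit", nrow(fx$features))),
               "2 classes")
  expect_error(train_activity_model(fx$features,
                                    rep(c("sit", "jog"), length.out = nrow(fx$features))),
               "unknown activity")
  expect_identical(length(predict_activity(model,
                                           fx$features[0, , drop = FALSE])), 0L)
})

test_that("confusion matrix and F1 bookkeeping are consistent", {
  truth <- c("sit", "sit", "walk", "walk", "run", "run")
  pred <- c("sit", "walk", "walk", "walk", "run", "sit")
  cm <- confusion_matrix(truth, pred, classes = c("sit", "walk", "run"))
  expect_equal(sum(cm), 6)
  expect_equal(as.vector(rowSums(cm)), c(2, 2, 2))  # row sums = class counts
  sc <- f1_scores(cm)
  expect_true(all(sc$per_class$f1 >= 0 & sc$per_class$f1 <= 1))
  expect_equal(sc$accuracy, 4 / 6)
  # weighted F1 equals support-weighted mean of per-class F1
  expect_equal(sc$f1_weighted,
               sum(sc$per_class$f1 * sc$per_class$support) / 6)
})

test_that("stratified 10-fold CV separates folds and scores a separable fixture perfectly", {
  fx <- separable_features(n_per_class = 40)
  ev <- evaluate_kfold(fx$features, fx$labels, k = 10, seed = 3)
  expect_equal(ev$f1_weighted, 1.0)
  expect_true(all(ev$confusion[upper.tri(ev$confusion)] == 0) &&
                all(ev$confusion[lower.tri(ev$confusion)] == 0))

  # per-class fold sizes differ by at most one
  for (cl in unique(fx$labels)) {
    sizes <- table(ev$folds[fx$labels == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  # pooled confusion matrix covers every window exactly once
  expect_equal(sum(ev$confusion), nrow(fx$features))

  expect_error(evaluate_kfold(fx$features[1:45, ], fx$labels[1:45], k = 10),
               "fewer than k")
})

test_that("uniformly shuffled labels score at chance level", {
  fx <- separable_features(n_per_class = 40,
                           classes = c("sit", "stand", "walk", "run"))
  set.seed(17)
  shuffled <- sample(fx$labels)
  ev <- evaluate_kfold(fx$features, shuffled, k = 10, seed = 17)
  expect_lt(abs(ev$f1_weighted - 0.25), 0.1)  # 4 balanced classes
})

test_that("leave-one-person-out folds track subjects and exchangeable subjects match within-subject fit", {
  fx <- separable_features(n_per_class = 30)
  # two identical synthetic subjects: duplicate the feature block
  features <- rbind(fx$features, fx$features)
  labels <- c(fx$labels, fx$labels)
  subjects <- rep(c("A", "B"), each = nrow(fx$features))
  ev <- evaluate_lopo(features, labels, subjects, seed = 5)
  expect_equal(length(unique(ev$folds)), 2)
  expect_equal(nrow(ev$per_subject), 2)
  expect_equal(ev$f1_weighted, 1.0)  # exchangeable subjects: no degradation

  expect_error(evaluate_lopo(features, labels, rep("A", length(labels))),
               "2 subjects")
  expect_error(evaluate_lopo(features, labels, NULL), "subject id")

  # grouped reporting pools the requested subjects
  ev2 <- evaluate_lopo(features, labels, subjects,
                       group_by = c(A = "g1", B = "g2"), seed = 5)
  expect_named(ev2$per_group, c("g1", "g2"))
  expect_equal(sum(ev2$per_group$g1$confusion), nrow(fx$features))
})
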