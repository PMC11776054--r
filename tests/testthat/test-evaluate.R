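make_cm <- function(counts, classes = LETTERS[seq_len(nrow(counts))]) {
  truth <- rep(rep(classes, each = length(classes)), times = as.vector(t(counts)))
  pred <- rep(rep(classes, times = length(classes)), times = as.vector(t(counts)))
  confusion_matrix(truth, pred, classes = classes)
}

test_that("confusion matrices count truth rows and prediction columns", {
  cm <- confusion_matrix(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(unclass(cm)[, ], matrix(c(1L, 0L, 1L, 2L), 2,
                                       dimnames = list(truth = c("A", "B"),
                                                       predicted = c("A", "B"))))
  expect_equal(sum(cm), 4)
  expect_error(confusion_matrix(character(), character()),
               class = "ligandpath_undefined_metric")
  expect_error(confusion_matrix("A", "C", classes = c("A", "B")), "outside")
})

test_that("balanced accuracy averages per-class recall over present classes", {
  expect_equal(balanced_accuracy(make_cm(diag(c(3, 5, 2)))), 1.0)
  expect_equal(balanced_accuracy(make_cm(rbind(c(8, 2), c(3, 7)))), 0.75)

  # constant-majority predictor over 9 present classes: 1/9
  truth <- rep(paste0("T", 1:9), times = c(20, 10, 3, 3, 2, 2, 5, 2, 2))
  cm <- confusion_matrix(truth, rep("T1", length(truth)))
  expect_equal(balanced_accuracy(cm), 1 / 9)

  # classes absent from the truth are excluded from the average
  cm2 <- confusion_matrix(c("A", "A"), c("A", "B"), classes = c("A", "B", "C"))
  expect_equal(balanced_accuracy(cm2), 0.5)
})

test_that("multiclass MCC follows the count formula with zero-denominator 0", {
  expect_equal(mcc(make_cm(diag(c(4, 4)))), 1.0)

  cm <- make_cm(rbind(c(6, 2), c(1, 7)))
  expect_equal(mcc(cm), 80 / sqrt(16128))
  expect_equal(mcc(cm), oracle_mcc(unclass(cm)))

  # constant predictor: zero-denominator convention
  truth <- rep(c("A", "B"), times = c(8, 2))
  expect_equal(mcc(confusion_matrix(truth, rep("A", 10))), 0)
})

test_that("BA and MCC match direct arithmetic on random confusion matrices", {
  withr::with_seed(53, {
    for (i in 1:100) {
      k <- sample(2:6, 1)
      counts <- matrix(rpois(k * k, lambda = 4), k)
      counts[1, 1] <- counts[1, 1] + 1  # at least one sample
      while (any(rowSums(counts) == 0)) counts <- counts + 1
      cm <- make_cm(counts)
      expect_equal(balanced_accuracy(cm), oracle_ba(unclass(cm)))
      expect_equal(mcc(cm), oracle_mcc(unclass(cm)))
    }
  })
})

test_that("ROC curves are monotone from (0,0) to (1,1) with pair-count AUC", {
  r <- roc_curve(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.3), positive = 1)
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[1], 0)
  expect_equal(tail(r$points$fpr, 1), 1)
  expect_equal(tail(r$points$tpr, 1), 1)

  # perfectly separating scores
  expect_equal(roc_curve(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), positive = 1)$auc, 1.0)
  # all scores identical: tie convention gives 0.5
  expect_equal(roc_curve(c(1, 0, 1, 0), rep(0.5, 4), positive = 1)$auc, 0.5)
  # one class absent
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3), positive = 1),
               class = "ligandpath_undefined_roc")

  withr::with_seed(67, {
    for (i in 1:100) {
      n <- sample(4:50, 1)
      truth <- c("p", "n", sample(c("p", "n"), n - 2, replace = TRUE))
      score <- round(runif(n), sample(1:3, 1))  # induce ties
      r <- roc_curve(truth, score, positive = "p")
      expect_equal(r$auc, oracle_auc(truth, score, "p"))
      expect_true(all(diff(r$points$fpr) >= 0))
      expect_true(all(diff(r$points$tpr) >= 0))
    }
  })
})

test_that("ROC AUC agrees with an independent implementation", {
  withr::with_seed(71, {
    truth <- sample(c("primary", "secondary"), 60, replace = TRUE)
    truth[1:2] <- c("primary", "secondary")
    score <- runif(60)
  })
  r <- roc_curve(truth, score, positive = "primary")
  ref <- pROC::roc(response = truth, predictor = score,
                   levels = c("secondary", "primary"), direction = "<",
                   quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("binary collapse sends T1/T2/T7 to primary, the rest to secondary", {
  expect_equal(collapse_to_binary("T7"), "primary")
  expect_equal(collapse_to_binary("T10"), "secondary")
  v <- c("T1", "T3", "T2", "T9", "T7", "T10")
  out <- collapse_to_binary(v)
  expect_equal(out, c("primary", "secondary", "primary", "secondary",
                      "primary", "secondary"))
  expect_length(out, length(v))
  expect_error(collapse_to_binary("T11"), class = "ligandpath_invalid_label")

  # protocol property: collapse of arbitrary T1..T10 vectors always scoreable
  withr::with_seed(83, {
    for (i in 1:20) {
      lab <- sample(paste0("T", 1:10), 30, replace = TRUE)
      pred <- sample(paste0("T", 1:10), 30, replace = TRUE)
      ct <- collapse_to_binary(lab); cp <- collapse_to_binary(pred)
      expect_true(all(c(ct, cp) %in% c("primary", "secondary")))
      cm <- confusion_matrix(ct, cp, classes = c("primary", "secondary"))
      expect_gte(balanced_accuracy(cm), 0)
      expect_lte(balanced_accuracy(cm), 1)
      expect_gte(mcc(cm), -1)
      expect_lte(mcc(cm), 1)
    }
  })
})

test_that("evaluation reports are self-consistent with their confusion matrix", {
  sys <- build_toy_system(5, 2, seed = 1)
  ds <- generate_dataset(sys, 80, config = walker_config(seed = 3))
  sp <- split_multiclass(ds, seed = 1)
  m <- train_model(sp$train, "multiclass",
                   hyperparameters = list(n_estimators = 60), seed = 1)
  rep <- evaluate_model(m, sp$test)

  expect_equal(rep$ba, oracle_ba(unclass(rep$confusion)))
  expect_equal(rep$mcc, oracle_mcc(unclass(rep$confusion)))
  expect_equal(rep$n, sum(rep$confusion))

  # a model scored against its own predictions is perfect
  self_test <- sp$test
  self_test$label <- predict(m, sp$test)$.pred_class
  rep_self <- evaluate_model(m, self_test)
  expect_equal(rep_self$ba, 1)
  expect_equal(rep_self$mcc, 1)
})

test_that("baseline evaluation reproduces the reference BA/MCC values", {
  sys <- build_toy_system(3, 2, seed = 1)
  ds <- generate_dataset(sys, 50, class_weights = c(T1 = 0.75, T3 = 0.25),
                         config = walker_config(seed = 2))
  ds$label <- collapse_to_binary(ds$label)  # T1 -> primary, T3 -> secondary
  m <- baseline_model(ds)
  rep <- evaluate_model(m, ds)
  expect_equal(rep$ba, 0.50)
  expect_equal(rep$mcc, 0.00)
})

test_that("binary reports include a ROC curve from primary-class scores", {
  sys <- build_toy_system(9, 2, seed = 1)
  ds <- generate_dataset(sys, 80, config = walker_config(seed = 4))
  sp <- split_binary(ds, seed = 1)
  m <- train_model(sp$train, "binary",
                   hyperparameters = list(n_estimators = 30), seed = 1)
  rep <- evaluate_model(m, sp$test)
  expect_s3_class(rep$roc, "roc_result")
  expect_true(rep$auc >= 0 && rep$auc <= 1)

  # multiclass model scored on the binary task via collapse
  m2 <- train_model(sp$train, "multiclass",
                    hyperparameters = list(n_estimators = 60), seed = 1)
  rep2 <- evaluate_model(m2, sp$test, collapse = TRUE)
  expect_setequal(rownames(rep2$confusion), c("primary", "secondary"))
  expect_equal(rep2$ba, oracle_ba(unclass(rep2$confusion)))
})

test_that("per-subset breakdown covers each (ligand, variant) cell", {
  sys <- build_toy_system(3, 2, seed = 1)
  ds <- generate_dataset(sys, 60, config = walker_config(seed = 5))
  ds$ligand <- rep(c("CO", "H2"), each = 30)
  sp <- split_multiclass(ds, seed = 1)
  m <- train_model(sp$train, "multiclass",
                   hyperparameters = list(n_estimators = 40), seed = 1)
  rep <- evaluate_model(m, sp$test)
  expect_setequal(rep$by_subset$ligand, unique(sp$test$ligand))
  for (i in seq_len(nrow(rep$by_subset))) {
    rows <- rep$predictions[sp$test$ligand == rep$by_subset$ligand[i], ]
    cm <- confusion_matrix(rows$truth, rows$.pred_class)
    expect_equal(rep$by_subset$ba[i], balanced_accuracy(cm))
  }
})

test_that("report files are written and tidiers summarize reports", {
  sys <- build_toy_system(3, 2, seed = 1)
  ds <- generate_dataset(sys, 40, config = walker_config(seed = 6))
  m <- baseline_model(ds)
  rep <- evaluate_model(m, ds)

  tf_json <- withr::local_tempfile(fileext = ".json")
  tf_cm <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json = tf_json, confusion_csv = tf_cm)
  j <- jsonlite::read_json(tf_json)
  expect_equal(j$n, rep$n)
  expect_equal(j$ba, rep$ba, tolerance = 1e-12)

  g <- generics::glance(rep)
  expect_named(g, c("mode", "n", "ba", "mcc", "auc"))
  td <- generics::tidy(rep$confusion)
  expect_equal(sum(td$n), rep$n)
})
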