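# small shared fixture: separable 2-tunnel / 9-tunnel synthetic sets
make_ds <- function(n, n_tunnels = 3, seed = 1, weights = NULL, roam = 0) {
  sys <- build_toy_system(n_tunnels, 2, seed = 1)
  cfg <- walker_config(seed = seed, roam_probability = roam)
  if (is.null(weights)) {
    generate_dataset(sys, n, config = cfg)
  } else {
    generate_dataset(sys, n, class_weights = weights, config = cfg)
  }
}

test_that("three-way splits hit the 70:15:15 ratio and stay disjoint", {
  ds <- make_ds(100)
  sp <- split_binary(ds, seed = 1)
  expect_named(sp, c("train", "validation", "test"))
  expect_equal(vapply(sp, nrow, 1L), c(train = 70, validation = 15, test = 15))

  # disjoint and exhaustive (trajectories tagged by feature fingerprint)
  all_rows <- dplyr::bind_rows(sp)
  expect_equal(nrow(all_rows), nrow(ds))
  expect_equal(dplyr::arrange_all(all_rows), dplyr::arrange_all(ds))

  # same seed twice: identical partitions; different seed: different
  sp2 <- split_binary(ds, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_binary(ds, seed = 2)
  expect_false(identical(sp$train, sp3$train))
})

test_that("splits are stratified on ligand within one row", {
  ds <- make_ds(200)
  # emulate the 92%/8% two-ligand composition
  ds$ligand <- rep(c("CO", "H2"), times = c(184, 16))
  sp <- split_binary(ds, seed = 3)
  for (part in sp) {
    h2 <- sum(part$ligand == "H2")
    expect_lte(abs(h2 - 0.08 * nrow(part)), 1)
  }

  # a stratum smaller than the partition count downgrades with a warning
  ds$ligand <- c(rep("CO", 198), "H2", "O2")
  expect_warning(split_binary(ds, seed = 1), "unstratified")
})

test_that("two-way splits are 70:30 and flag singleton classes", {
  ds <- make_ds(100)
  sp <- split_multiclass(ds, seed = 1)
  expect_equal(vapply(sp, nrow, 1L), c(train = 70, test = 30))
  expect_identical(sp, split_multiclass(ds, seed = 1))

  ds_single <- ds
  ds_single$label[1] <- "T9"
  expect_warning(split_multiclass(ds_single, seed = 1), "single row")
})

test_that("oversampling balances classes by duplicating originals only", {
  ds <- tibble::tibble(
    label = c(rep("A", 10), rep("B", 3)),
    L1 = seq(0, 1, length.out = 13), L2 = rev(seq(0, 1, length.out = 13))
  )
  out <- oversample(ds, seed = 1)
  expect_equal(as.vector(table(out$label)), c(10, 10))
  # originals retained verbatim
  expect_identical(out[1:13, ], ds)

  # already balanced: unchanged
  bal <- ds[c(1:3, 11:13), ]
  expect_identical(oversample(bal, seed = 1), bal)

  # every synthetic row is a duplicate of an original of the same class
  ds3 <- tibble::tibble(
    label = c(rep("T1", 50), rep("T3", 2), rep("T8", 1)),
    L1 = runif(53), L2 = runif(53)
  )
  out3 <- oversample(ds3, seed = 1)
  expect_equal(as.vector(table(out3$label)), c(50, 50, 50))
  synth <- out3[-seq_len(53), ]
  for (i in seq_len(nrow(synth))) {
    src <- ds3[ds3$label == synth$label[i], ]
    expect_true(any(src$L1 == synth$L1[i] & src$L2 == synth$L2[i]))
  }
})

test_that("training refuses degenerate input and recovers separable data", {
  ds <- make_ds(60)
  single <- ds[ds$label == ds$label[1], ]
  expect_error(train_model(single, "multiclass"), "single class")

  m <- train_model(ds, "multiclass",
                   hyperparameters = list(n_estimators = 100), seed = 1)
  pred <- predict(m, ds)
  cm <- confusion_matrix(ds$label, pred$.pred_class)
  expect_equal(balanced_accuracy(cm), 1.0)
})

test_that("training and prediction are deterministic for a fixed seed", {
  ds <- make_ds(60)
  probe <- make_ds(20, seed = 99)
  m1 <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 60), seed = 1)
  m2 <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 60), seed = 1)
  expect_identical(predict(m1, probe), predict(m2, probe))

  b1 <- train_model(ds, "binary", hyperparameters = list(n_estimators = 30), seed = 1)
  b2 <- train_model(ds, "binary", hyperparameters = list(n_estimators = 30), seed = 1)
  expect_identical(predict(b1, probe), predict(b2, probe))
})

test_that("binary scheme collapses labels and fits adaptive boosting", {
  ds <- make_ds(80, n_tunnels = 9, seed = 2)
  m <- train_model(ds, "binary", hyperparameters = list(n_estimators = 40), seed = 1)
  expect_equal(m$family, "adaboost")
  expect_setequal(m$classes, c("primary", "secondary"))
  pred <- predict(m, ds)
  expect_true(all(pred$.pred_class %in% c("primary", "secondary")))
  # class scores renormalized rowwise
  expect_equal(pred$.pred_primary + pred$.pred_secondary,
               rep(1, nrow(pred)), tolerance = 1e-9)
})

test_that("T10 rows are dropped from multiclass training with a warning", {
  ds <- make_ds(60)
  ds$label[1:5] <- "T10"
  expect_warning(
    m <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 40)),
    "T10"
  )
  expect_false("T10" %in% m$classes)
})

test_that("prediction enforces the feature schema", {
  ds <- make_ds(40)
  m <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 40))
  bad <- ds; bad$L74 <- NULL
  expect_error(predict(m, bad), class = "ligandpath_schema_error")
  expect_error(predict(m, bad), "L74")
  bad2 <- ds; bad2$S999 <- 0.5
  expect_error(predict(m, bad2), "S999")

  # column order does not matter
  shuffled <- ds[, c(1:3, rev(seq(4, ncol(ds))))]
  expect_identical(predict(m, ds), predict(m, shuffled))

  # all-zero row predicts some valid class without crashing
  zero <- ds[1, ]
  zero[feature_cols(zero)] <- 0
  p <- predict(m, zero)
  expect_true(p$.pred_class %in% m$classes)
})

test_that("baseline model predicts the dominant class with lexicographic ties", {
  ds <- tibble::tibble(label = c(rep("A", 7), rep("B", 3)), L1 = runif(10))
  m <- baseline_model(ds)
  expect_equal(unique(predict(m, ds)$.pred_class), "A")

  tie <- tibble::tibble(label = c(rep("B", 5), rep("A", 5)), L1 = runif(10))
  expect_equal(unique(predict(baseline_model(tie), tie)$.pred_class), "A")
})

test_that("grid search is exhaustive with deterministic tie-breaking", {
  ds <- make_ds(60)
  one <- tibble::tibble(n_estimators = 30)
  res <- tune_hyperparameters(ds, one, "multiclass", folds = 3, seed = 1)
  expect_equal(res$best$n_estimators, 30)

  two_same <- tibble::tibble(n_estimators = c(30, 30), max_depth = c(10, 10))
  res2 <- tune_hyperparameters(ds, two_same, "multiclass", folds = 3, seed = 1)
  expect_equal(res2$results$score[1], res2$results$score[2])
  expect_identical(res2$best, as.list(two_same[1, ]))
})

test_that("grid search identifies a clearly superior depth", {
  # non-linearly-separable labels: XOR of two planted features
  withr::with_seed(31, {
    n <- 120
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
    ds <- tibble::tibble(
      label = ifelse(xor(a == 1, b == 1), "T1", "T3"),
      L1 = a + runif(n, 0, 0.2), L2 = b + runif(n, 0, 0.2),
      L3 = runif(n)
    )
  })
  grid <- tibble::tibble(n_estimators = c(50, 50), max_depth = c(1, 30))
  res <- tune_hyperparameters(ds, grid, "multiclass", folds = 3, seed = 1)
  expect_equal(res$best$max_depth, 30)

  # fold reduction warns when the smallest class is tiny
  ds_small <- ds[c(which(ds$label == "T1"), which(ds$label == "T3")[1:3]), ]
  expect_warning(
    tune_hyperparameters(ds_small, grid[2, ], "multiclass", folds = 5, seed = 1),
    "reducing folds"
  )
})

test_that("binary tuning scores on the validation partition", {
  ds <- make_ds(80, n_tunnels = 9, seed = 2)
  # the imbalanced fixture may leave a singleton tunnel; that warning is
  # exercised elsewhere
  sp <- suppressWarnings(split_binary(ds, seed = 1))
  grid <- tibble::tibble(n_estimators = c(20, 40))
  res <- tune_hyperparameters(sp$train, grid, "binary",
                              validation = sp$validation, seed = 1)
  expect_equal(nrow(res$results), 2)
  expect_true(res$best$n_estimators %in% c(20, 40))
  expect_error(tune_hyperparameters(sp$train, grid, "binary", seed = 1),
               "validation")
})

test_that("feature importance is a normalized ranking of planted signal", {
  # only 5 residues carry class signal
  withr::with_seed(41, {
    n <- 150
    lab <- sample(c("T1", "T2", "T3"), n, replace = TRUE)
    signal <- sapply(c("T1", "T2", "T3"), function(cl) as.numeric(lab == cl))
    ds <- tibble::tibble(label = lab)
    ds$L1 <- signal[, 1] * 0.9 + runif(n, 0, 0.05)
    ds$L2 <- signal[, 2] * 0.9 + runif(n, 0, 0.05)
    ds$L3 <- signal[, 3] * 0.9 + runif(n, 0, 0.05)
    ds$L4 <- signal[, 1] * 0.8 + runif(n, 0, 0.05)
    ds$L5 <- signal[, 2] * 0.8 + runif(n, 0, 0.05)
    for (k in 6:20) ds[[paste0("L", k)]] <- runif(n, 0, 1)
    ds$L21 <- 0.5  # constant feature
  })
  m <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 200), seed = 1)
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_setequal(imp$residue[1:5], paste0("L", 1:5))
  expect_equal(imp$importance[imp$residue == "L21"], 0)

  expect_error(feature_importance(baseline_model(ds)),
               class = "ligandpath_unsupported_model")
})

test_that("models survive a save/load round trip with schema checks", {
  ds <- make_ds(40)
  m <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 30))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  m2 <- load_model(tf)
  expect_identical(predict(m, ds), predict(m2, ds))

  saveRDS(list(not = "a model"), tf)
  expect_error(load_model(tf), "schema")
})

test_that("tidy and glance summarize models broom-style", {
  ds <- make_ds(40)
  m <- train_model(ds, "multiclass", hyperparameters = list(n_estimators = 30))
  td <- generics::tidy(m)
  expect_named(td, c("residue", "importance"))
  g <- generics::glance(m)
  expect_equal(g$family, "random_forest")
  expect_equal(g$n_train, 40)
})
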