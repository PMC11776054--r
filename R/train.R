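#' Classification schemes
#'
#' Two schemes mirror the two pathway-assignment tasks.  The *binary* scheme
#' separates the high-traffic primary tunnels (T1, T2 and the adjacent T7)
#' from all secondary pathways (T3--T6, T8--T10); it is fit with adaptive
#' boosting.  The *multiclass* scheme distinguishes the nine individual
#' tunnels T1--T9 and is fit with a random forest; T10 -- a route observed
#' only in the external-test enzyme -- is never a trainable class and is
#' excluded from multiclass training (rows with T10 labels in a test set are
#' necessarily misclassified).
#'
#' @param mode `"binary"` or `"multiclass"`.
#' @return A `class_scheme` object.
#' @export
class_scheme <- function(mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode,
      primary = c("T1", "T2", "T7"),
      pathways = paste0("T", 1:10),
      trainable = if (mode == "binary") c("primary", "secondary") else paste0("T", 1:9)
    ),
    class = "class_scheme"
  )
}

scheme_labels <- function(scheme, labels) {
  if (scheme$mode == "binary") {
    if (all(labels %in% c("primary", "secondary"))) return(labels)
    collapse_to_binary(labels)
  } else {
    labels
  }
}

#' Default model hyperparameters
#'
#' The grid-search-selected settings used for the final models: adaptive
#' boosting with `n_estimators = 500`, `learning_rate = 0.05` (binary);
#' random forest with `n_estimators = 500`, `max_depth = 30`,
#' `max_samples = 0.9` (multiclass).  All training uses `seed = 1` by
#' default.
#'
#' @param mode `"binary"` or `"multiclass"`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    list(n_estimators = 500, learning_rate = 0.05, max_depth = 1)
  } else {
    list(n_estimators = 500, max_depth = 30, max_samples = 0.9,
         min_node_size = 1)
  }
}

#' Train a pathway classifier
#'
#' Oversamples the training partition to equal class counts, then fits the
#' scheme's designated ensemble: adaptive boosting (SAMME over depth-1 CART
#' stumps) for the binary scheme, a random forest (via ranger, impurity
#' importance, probability trees) for the multiclass scheme.  Deterministic
#' for a fixed seed.
#'
#' @param train Training feature table (`label` column + residue-key
#'   feature columns).  For the multiclass scheme, T10 rows are dropped
#'   with a warning.
#' @param scheme A [class_scheme()], or `"binary"` / `"multiclass"`.
#' @param hyperparameters Named list overriding
#'   [default_hyperparameters()] entries.
#' @param seed Integer seed (training and oversampling); default 1.
#' @param oversample Logical; balance classes by random oversampling before
#'   fitting (default `TRUE`).
#' @return A `path_model`.
#' @examples
#' sys <- build_toy_system(3, 2, seed = 1)
#' ds <- generate_dataset(sys, 60, config = walker_config(seed = 1))
#' m <- train_model(ds, "multiclass",
#'                  hyperparameters = list(n_estimators = 50), seed = 1)
#' predict(m, ds[1:3, ])
#' @export
train_model <- function(train, scheme = class_scheme("multiclass"),
                        hyperparameters = NULL, seed = 1, oversample = TRUE) {
  if (is.character(scheme)) scheme <- class_scheme(scheme)
  train <- as_tibble(train)
  if (!"label" %in% names(train) || nrow(train) == 0) {
    abort("`train` must be a nonempty feature table with a `label` column.")
  }
  labels <- scheme_labels(scheme, as.character(train$label))
  if (scheme$mode == "multiclass" && any(labels == "T10")) {
    warn("T10 is not a trainable class; dropping its rows from the training set.")
    keep <- labels != "T10"
    train <- train[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) {
    abort("Training set contains a single class; cannot fit a classifier.")
  }
  hp <- modifyList(default_hyperparameters(scheme$mode),
                   hyperparameters %||% list())

  fc <- feature_cols(train)
  if (length(fc) == 0) abort("No residue-key feature columns found.")
  work <- dplyr::bind_cols(tibble(label = labels), train[, fc, drop = FALSE])
  if (oversample) work <- oversample(work, seed = seed)

  x <- feature_matrix(work, fc)
  y <- factor(work$label)

  fit <- if (scheme$mode == "binary") {
    fit_adaboost(x, y, n_estimators = hp$n_estimators,
                 learning_rate = hp$learning_rate,
                 max_depth = hp$max_depth, seed = seed)
  } else {
    df <- as.data.frame(x)
    df$.y <- y
    ranger::ranger(
      dependent.variable.name = ".y", data = df,
      num.trees = hp$n_estimators, max.depth = hp$max_depth,
      sample.fraction = hp$max_samples, min.node.size = hp$min_node_size,
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    )
  }

  new_path_model(
    family = if (scheme$mode == "binary") "adaboost" else "random_forest",
    scheme = scheme, hyperparameters = hp, fit = fit,
    feature_cols = fc, classes = levels(y), seed = seed,
    n_train = nrow(train)
  )
}

new_path_model <- function(family, scheme, hyperparameters, fit, feature_cols,
                           classes, seed, n_train) {
  structure(
    list(family = family, scheme = scheme, hyperparameters = hyperparameters,
         fit = fit, feature_cols = feature_cols, classes = classes,
         seed = seed, n_train = n_train, schema_version = 1L),
    class = "path_model"
  )
}

#' @export
print.path_model <- function(x, ...) {
  cat("<path_model> ", x$family, " (", x$scheme$mode, "), ",
      length(x$classes), " classes [", paste(x$classes, collapse = ", "),
      "], ", length(x$feature_cols), " features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Dominant-class baseline model
#'
#' A dummy classifier that assigns every input to the most frequent training
#' class (ties broken lexicographically).  Its balanced accuracy on a test
#' set covering K classes is 1/K and its MCC is 0 -- the reference point all
#' trained models must beat.
#'
#' @param train Feature table with a `label` column.
#' @param scheme Optional [class_scheme()]; when given, labels are
#'   collapsed/restricted accordingly.
#' @return A `path_model` with family `"dummy"`.
#' @export
baseline_model <- function(train, scheme = NULL) {
  train <- as_tibble(train)
  if (!"label" %in% names(train) || nrow(train) == 0) {
    abort("`train` must be a nonempty feature table with a `label` column.")
  }
  labels <- as.character(train$label)
  if (!is.null(scheme)) {
    if (is.character(scheme)) scheme <- class_scheme(scheme)
    labels <- scheme_labels(scheme, labels)
  }
  counts <- table(labels)
  classes <- sort(names(counts))
  # which.max over lexicographically sorted classes breaks ties deterministically
  majority <- classes[which.max(as.numeric(counts[classes]))]
  new_path_model(
    family = "dummy",
    scheme = scheme %||% class_scheme("multiclass"),
    hyperparameters = list(strategy = "most_frequent"),
    fit = list(majority = majority),
    feature_cols = feature_cols(train), classes = classes,
    seed = NA_integer_, n_train = nrow(train)
  )
}

#' Predict pathway labels
#'
#' @param object A `path_model`.
#' @param new_data Feature table; its residue-key columns must match the
#'   model's training features (any order).  Missing or extra feature
#'   columns raise a schema error naming the offending keys.
#' @param ... Unused.
#' @return Tibble with `.pred_class` and one `.pred_<class>` score column
#'   per class; scores are in \[0, 1\] and each row sums to 1.
#' @export
predict.path_model <- function(object, new_data, ...) {
  new_data <- as_tibble(new_data)
  fc_new <- feature_cols(new_data)
  missing <- setdiff(object$feature_cols, fc_new)
  extra <- setdiff(fc_new, object$feature_cols)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "Feature schema mismatch.",
      if (length(missing)) paste0(" Missing column(s): ",
                                  paste(missing, collapse = ", "), "."),
      if (length(extra)) paste0(" Unexpected column(s): ",
                                paste(extra, collapse = ", "), ".")
    ), class = "ligandpath_schema_error")
  }
  x <- feature_matrix(new_data, object$feature_cols)  # reorders to fit order

  if (object$family == "dummy") {
    prob <- matrix(0, nrow = nrow(x), ncol = length(object$classes),
                   dimnames = list(NULL, object$classes))
    prob[, object$fit$majority] <- 1
    cls <- rep(object$fit$majority, nrow(x))
  } else if (object$family == "adaboost") {
    pr <- predict_adaboost(object$fit, x)
    prob <- pr$prob
    cls <- pr$class
  } else {
    pr <- predict(object$fit, data = as.data.frame(x), num.threads = 1)
    prob <- pr$predictions[, object$classes, drop = FALSE]
    prob <- prob / rowSums(prob)
    cls <- object$classes[max.col(prob, ties.method = "first")]
  }

  out <- tibble(.pred_class = cls)
  colnames(prob) <- paste0(".pred_", colnames(prob))
  dplyr::bind_cols(out, as_tibble(prob))
}

#' Grid search for hyperparameters
#'
#' Exhaustively evaluates a hyperparameter grid.  For the binary scheme each
#' candidate is scored on the held-out validation partition; for the
#' multiclass scheme by stratified k-fold cross-validation (5 folds by
#' default) on the training partition.  The scoring metric is balanced
#' accuracy.  Ties are broken deterministically in favor of the first grid
#' row.
#'
#' @param train Training feature table.
#' @param grid Data frame: one row per candidate, columns named after
#'   [default_hyperparameters()] entries.
#' @param scheme A [class_scheme()] or mode string.
#' @param validation Validation feature table (required for binary mode).
#' @param folds Number of CV folds for multiclass mode; reduced with a
#'   warning if the smallest class has fewer rows.
#' @param seed Integer seed.
#' @return List: `best` (named list of the winning hyperparameters),
#'   `results` (grid with a `score` column).
#' @export
tune_hyperparameters <- function(train, grid, scheme = class_scheme("multiclass"),
                                 validation = NULL, folds = 5, seed = 1) {
  if (is.character(scheme)) scheme <- class_scheme(scheme)
  grid <- as_tibble(grid)
  if (nrow(grid) == 0) abort("`grid` must have at least one row.")
  train <- as_tibble(train)

  score_one <- function(hp) {
    if (scheme$mode == "binary") {
      if (is.null(validation)) {
        abort("Binary tuning scores on a validation partition; supply `validation`.")
      }
      m <- train_model(train, scheme, hyperparameters = hp, seed = seed)
      truth <- scheme_labels(scheme, as.character(validation$label))
      pred <- predict(m, validation)$.pred_class
      balanced_accuracy(confusion_matrix(truth, pred))
    } else {
      labels <- as.character(train$label)
      labels[labels == "T10"] <- NA
      keep <- !is.na(labels)
      dat <- train[keep, , drop = FALSE]
      labels <- labels[keep]
      k <- folds
      min_class <- min(table(labels))
      if (min_class < k) {
        warn(paste0("Smallest class has ", min_class, " rows; reducing folds from ",
                    k, " to ", max(2, min_class), "."))
        k <- max(2, min_class)
      }
      fold_id <- stratified_folds(labels, k, seed)
      scores <- purrr::map_dbl(seq_len(k), function(f) {
        m <- train_model(dat[fold_id != f, , drop = FALSE], scheme,
                         hyperparameters = hp, seed = seed)
        truth <- labels[fold_id == f]
        pred <- predict(m, dat[fold_id == f, , drop = FALSE])$.pred_class
        balanced_accuracy(confusion_matrix(truth, pred))
      })
      mean(scores)
    }
  }

  results <- grid
  results$score <- purrr::map_dbl(seq_len(nrow(grid)), function(i) {
    score_one(as.list(grid[i, , drop = FALSE]))
  })
  best_i <- which.max(results$score)  # first max: deterministic tie-break
  list(best = as.list(grid[best_i, , drop = FALSE]), results = results)
}

stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Feature importance of a tree ensemble
#'
#' Mean-decrease-in-impurity importance, normalized to sum to 1, used to
#' identify which ligand-residue contacts drive pathway assignment.
#'
#' @param model A `path_model` with a tree-ensemble family.
#' @return Tibble (`residue`, `importance`) sorted by decreasing
#'   importance; importances are nonnegative and sum to 1.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "path_model"))
  if (model$family == "dummy") {
    abort("Feature importance is only defined for tree-ensemble models.",
          class = "ligandpath_unsupported_model")
  }
  raw <- if (model$family == "adaboost") {
    importance_adaboost(model$fit)
  } else {
    ranger::importance(model$fit)
  }
  imp <- setNames(numeric(length(model$feature_cols)), model$feature_cols)
  imp[names(raw)] <- pmax(raw, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tibble(residue = names(imp), importance = as.numeric(imp)) %>%
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Save / load a fitted model
#'
#' Persists the model as a versioned archive (estimator family,
#' hyperparameters, fitted state, feature column order, class scheme,
#' seed).  Loading refuses archives written under a different schema
#' version.
#'
#' @param model A `path_model`.
#' @param path File path.
#' @return `save_model()` the path invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "path_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "path_model") ||
      !identical(model$schema_version, 1L)) {
    abort("File is not a compatible path_model archive (schema version mismatch).")
  }
  model
}
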