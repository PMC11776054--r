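#' Evaluate a model on a test set
#'
#' Predicts the test partition and assembles the full evaluation report:
#' confusion matrix (rows = truth, columns = predicted), balanced accuracy,
#' MCC, a per-(ligand, variant) subset breakdown, and -- whenever the task
#' is binary -- the ROC curve and AUC using the primary-class score.  For a
#' multiclass model, `collapse = TRUE` first collapses both truth and
#' predictions to primary/secondary and scores the binary task.
#'
#' @param model A `path_model`.
#' @param test Feature table with a `label` column.
#' @param collapse Collapse multiclass predictions to the binary scheme
#'   before scoring (default `FALSE`).
#' @return An `evaluation_report`: `confusion`, `ba`, `mcc`, `auc`/`roc`
#'   (binary tasks), `by_subset` tibble, `predictions` tibble, `n`.
#' @examples
#' sys <- build_toy_system(3, 2, seed = 1)
#' ds <- generate_dataset(sys, 60, config = walker_config(seed = 1))
#' sp <- split_multiclass(ds, seed = 1)
#' m <- train_model(sp$train, "multiclass",
#'                  hyperparameters = list(n_estimators = 50))
#' evaluate_model(m, sp$test)
#' @export
evaluate_model <- function(model, test, collapse = FALSE) {
  stopifnot(inherits(model, "path_model"))
  test <- as_tibble(test)
  if (nrow(test) == 0 || !"label" %in% names(test)) {
    abort("`test` must be a nonempty feature table with a `label` column.")
  }

  truth <- as.character(test$label)
  if (model$scheme$mode == "binary" && !all(truth %in% c("primary", "secondary"))) {
    truth <- collapse_to_binary(truth)
  }
  pred_tbl <- predict(model, test)
  pred <- pred_tbl$.pred_class

  binary_task <- model$scheme$mode == "binary"
  if (collapse) {
    if (model$scheme$mode == "multiclass") {
      pred <- collapse_to_binary(pred)
      if (!all(truth %in% c("primary", "secondary"))) {
        truth <- collapse_to_binary(truth)
      }
    }
    binary_task <- TRUE
  }

  cm <- confusion_matrix(truth, pred)
  roc <- NULL
  auc <- NA_real_
  if (binary_task && all(c("primary", "secondary") %in% unique(truth))) {
    pos_score <- primary_score(model, pred_tbl, collapse)
    roc <- roc_curve(truth, pos_score, positive = "primary")
    auc <- roc$auc
  }

  subset_vars <- intersect(c("ligand", "variant"), names(test))
  by_subset <- if (length(subset_vars) > 0) {
    grp <- test[, subset_vars, drop = FALSE]
    grp$.truth <- truth
    grp$.pred <- pred
    grp %>%
      dplyr::group_by(dplyr::across(dplyr::all_of(subset_vars))) %>%
      dplyr::summarise(
        n = dplyr::n(),
        ba = balanced_accuracy(confusion_matrix(.data$.truth, .data$.pred)),
        mcc = mcc(confusion_matrix(.data$.truth, .data$.pred)),
        .groups = "drop"
      )
  } else {
    tibble()
  }

  structure(
    list(
      confusion = cm,
      ba = balanced_accuracy(cm),
      mcc = mcc(cm),
      roc = roc,
      auc = auc,
      by_subset = by_subset,
      predictions = dplyr::bind_cols(tibble(truth = truth), pred_tbl),
      n = length(truth),
      mode = if (binary_task) "binary" else "multiclass"
    ),
    class = "evaluation_report"
  )
}

# primary-class probability for ROC scoring
primary_score <- function(model, pred_tbl, collapse) {
  if (!collapse && ".pred_primary" %in% names(pred_tbl)) {
    return(pred_tbl$.pred_primary)
  }
  prim_cols <- intersect(paste0(".pred_", c("T1", "T2", "T7")), names(pred_tbl))
  if (length(prim_cols) > 0) {
    return(rowSums(pred_tbl[, prim_cols, drop = FALSE]))
  }
  if (".pred_primary" %in% names(pred_tbl)) return(pred_tbl$.pred_primary)
  # dummy model predicting a single class: constant scores
  as.numeric(pred_tbl$.pred_class == "primary")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$mode, " task, n = ", x$n,
      ", BA = ", sprintf("%.3f", x$ba),
      ", MCC = ", sprintf("%.3f", x$mcc),
      if (!is.na(x$auc)) paste0(", AUC = ", sprintf("%.3f", x$auc)),
      "\n", sep = "")
  invisible(x)
}

#' Write an evaluation report to files
#'
#' @param report An `evaluation_report`.
#' @param json,confusion_csv,roc_csv Optional output paths; each written
#'   only if non-`NULL`.  The JSON schema is versioned.
#' @return The report, invisibly.
#' @export
write_report <- function(report, json = NULL, confusion_csv = NULL,
                         roc_csv = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(confusion_csv)) {
    utils::write.csv(as.data.frame(unclass(report$confusion)), confusion_csv)
  }
  if (!is.null(roc_csv) && !is.null(report$roc)) {
    readr::write_csv(report$roc$points, roc_csv)
  }
  if (!is.null(json)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("Writing JSON reports requires the jsonlite package.")
    }
    payload <- list(
      schema_version = 1L,
      mode = report$mode,
      n = report$n,
      ba = report$ba,
      mcc = report$mcc,
      auc = if (is.na(report$auc)) NULL else report$auc,
      classes = rownames(report$confusion),
      confusion = unclass(report$confusion),
      by_subset = report$by_subset
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
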