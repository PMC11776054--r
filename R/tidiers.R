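#' Tidy a fitted pathway model
#'
#' Returns the per-residue feature importances (tree ensembles) as a tibble,
#' broom-style.
#'
#' @param x A `path_model`.
#' @param ... Unused.
#' @return Tibble with columns `residue`, `importance`.
#' @export
tidy.path_model <- function(x, ...) {
  feature_importance(x)
}

#' Glance at a fitted pathway model
#'
#' @param x A `path_model`.
#' @param ... Unused.
#' @return One-row tibble summarizing the fit.
#' @export
glance.path_model <- function(x, ...) {
  tibble(
    family = x$family,
    mode = x$scheme$mode,
    n_classes = length(x$classes),
    n_features = length(x$feature_cols),
    n_train = x$n_train,
    seed = x$seed
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-(ligand, variant) subset metrics as a tibble; if the
#'   test set had no subset metadata, the overall metrics as one row.
#' @export
tidy.evaluation_report <- function(x, ...) {
  if (nrow(x$by_subset) > 0) x$by_subset
  else tibble(n = x$n, ba = x$ba, mcc = x$mcc)
}

#' Glance at an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return One-row tibble: `mode`, `n`, `ba`, `mcc`, `auc`.
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble(mode = x$mode, n = x$n, ba = x$ba, mcc = x$mcc, auc = x$auc)
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return Long tibble with columns `truth`, `predicted`, `n`.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("truth", "predicted", "n")
  as_tibble(df)
}
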