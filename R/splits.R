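#' Stratified dataset splits
#'
#' `split_binary()` partitions a feature table into train/validation/test
#' sets (70:15:15 by default); `split_multiclass()` into train/test
#' (70:30).  Splits are stratified on the ligand species so each partition
#' keeps the global ligand proportions within rounding (in the real data CO
#' and H2 make up 92% and 8%); partitions are disjoint, their union is the
#' input, and a fixed seed reproduces them exactly.  A validation set is
#' only carved out for the binary task -- with the multiclass task's extreme
#' imbalance the minority pathways would be too ill-represented there, so
#' hyperparameters are tuned by cross-validation instead.
#'
#' @param data Feature table with a `label` column (see
#'   [generate_dataset()] / [read_feature_table()]).
#' @param ratios Partition proportions summing to 1.
#' @param stratify_by Column to stratify on; default `"ligand"`.  If a
#'   stratum has fewer rows than partitions the split downgrades to
#'   unstratified with a warning.
#' @param seed Integer seed.
#' @return Named list of tibbles: `train`, `validation`, `test` (binary) or
#'   `train`, `test` (multiclass).
#' @examples
#' sys <- build_toy_system(3, 2, seed = 1)
#' ds <- generate_dataset(sys, 40, config = walker_config(seed = 1))
#' sp <- split_multiclass(ds, seed = 1)
#' nrow(sp$train); nrow(sp$test)
#' @export
split_binary <- function(data, ratios = c(train = 0.70, validation = 0.15, test = 0.15),
                         stratify_by = "ligand", seed = 1) {
  split_stratified(data, ratios, stratify_by, seed,
                   names = c("train", "validation", "test"))
}

#' @rdname split_binary
#' @export
split_multiclass <- function(data, ratios = c(train = 0.70, test = 0.30),
                             stratify_by = "ligand", seed = 1) {
  split_stratified(data, ratios, stratify_by, seed, names = c("train", "test"))
}

split_stratified <- function(data, ratios, stratify_by, seed, names) {
  data <- as_tibble(data)
  if (length(ratios) != length(names)) {
    abort(paste0("`ratios` must have ", length(names), " entries."))
  }
  if (abs(sum(ratios) - 1) > 1e-8) abort("`ratios` must sum to 1.")
  n <- nrow(data)
  if (n < length(names)) abort("Fewer rows than partitions.")

  strata <- if (!is.null(stratify_by) && stratify_by %in% names(data)) {
    as.character(data[[stratify_by]])
  } else {
    rep("all", n)
  }
  counts <- table(strata)
  if (length(counts) > 1 && any(counts < length(names))) {
    warn("A stratum has fewer rows than partitions; falling back to an unstratified split.")
    strata <- rep("all", n)
  }
  if (!is.null(stratify_by) && length(unique(strata)) == 1 &&
      stratify_by %in% names(data)) {
    # single stratum: plain split (still deterministic)
  }

  assign <- integer(n)
  withr::with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      sizes <- largest_remainder(length(idx), ratios)
      part <- rep(seq_along(ratios), times = sizes)
      assign[idx] <- part
    }
  })
  singleton <- data %>%
    dplyr::count(.data$label) %>%
    dplyr::filter(.data$n == 1)
  if (nrow(singleton) > 0) {
    warn(paste0("Class(es) with a single row land entirely in one partition: ",
                paste(singleton$label, collapse = ", ")))
  }
  setNames(lapply(seq_along(ratios), function(p) data[assign == p, , drop = FALSE]),
           names)
}

# integer partition sizes matching ratios exactly (largest-remainder rounding)
largest_remainder <- function(n, ratios) {
  exact <- n * ratios / sum(ratios)
  sizes <- floor(exact)
  short <- n - sum(sizes)
  if (short > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1
  }
  as.integer(sizes)
}

#' Random oversampling of minority classes
#'
#' Evens out an imbalanced label distribution by duplicating rows of every
#' minority class (sampling with replacement, fixed seed) until all classes
#' match the majority count.  Original rows are always retained; every
#' synthetic row is an exact copy of an original row of the same class.
#' Apply only to a training partition, after splitting, so no duplicated
#' row can leak into validation or test data.
#'
#' @param data Feature table with a `label` column.
#' @param seed Integer seed.
#' @return Tibble with equal class counts (original rows first).
#' @examples
#' df <- tibble::tibble(label = c(rep("A", 10), rep("B", 3)), L1 = 1:13 / 13)
#' dplyr::count(oversample(df, seed = 1), label)
#' @export
oversample <- function(data, seed = 1) {
  data <- as_tibble(data)
  if (!"label" %in% names(data)) abort("`data` must have a `label` column.")
  counts <- table(data$label)
  target <- max(counts)
  extra_idx <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      need <- target - counts[[cl]]
      if (need == 0) return(integer())
      pool <- which(data$label == cl)
      pool[sample.int(length(pool), need, replace = TRUE)]
    }))
  })
  dplyr::bind_rows(data, data[extra_idx, , drop = FALSE])
}
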