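#' Residue keys
#'
#' Residues are identified by a *residue key*: the subunit tag (`"L"` for the
#' large subunit, `"S"` for the small subunit) followed by the author residue
#' number of the reference structure, e.g. `"L74"` or `"S267"`.  Keys serve as
#' feature-column names throughout the package, and the canonical column order
#' is sorted by (subunit, position).
#'
#' @param subunit Character vector of subunit tags.
#' @param position Integer vector of author residue numbers (1-based).
#' @return `residue_key()` returns a character vector of keys;
#'   `parse_residue_key()` a tibble with columns `key`, `subunit`, `position`;
#'   `sort_residue_keys()` the keys sorted by (subunit, position).
#' @examples
#' residue_key(c("L", "S"), c(74, 267))
#' sort_residue_keys(c("S12", "L7", "L100", "L74"))
#' @export
residue_key <- function(subunit, position) {
  if (length(subunit) == 1L) subunit <- rep(subunit, length(position))
  stopifnot(length(subunit) == length(position))
  if (!all(grepl("^[A-Za-z]+$", subunit))) {
    abort("Subunit tags must be alphabetic (e.g. \"L\", \"S\").")
  }
  pos <- as.integer(position)
  if (anyNA(pos) || any(pos < 1)) {
    abort("Residue positions must be positive integers.")
  }
  paste0(subunit, pos)
}

#' @rdname residue_key
#' @param key Character vector of residue keys such as `"L74"`.
#' @export
parse_residue_key <- function(key) {
  ok <- grepl("^[A-Za-z]+[0-9]+$", key)
  if (!all(ok)) {
    abort(paste0(
      "Malformed residue key(s): ",
      paste(unique(key[!ok]), collapse = ", ")
    ))
  }
  tibble(
    key = key,
    subunit = sub("[0-9]+$", "", key),
    position = as.integer(sub("^[A-Za-z]+", "", key))
  )
}

#' @rdname residue_key
#' @export
sort_residue_keys <- function(key) {
  p <- parse_residue_key(key)
  key[order(p$subunit, p$position)]
}

is_residue_key <- function(x) grepl("^[A-Za-z]+[0-9]+$", x)

#' Feature columns of a feature table
#'
#' Returns the columns of a feature table that hold per-residue contact
#' fractions, i.e. all columns whose name is a residue key, excluding the
#' reserved metadata columns (`label`, `ligand`, `variant`, `.traj_id`).
#'
#' @param data A data frame with residue-key feature columns.
#' @return Character vector of feature column names, in table order.
#' @export
feature_cols <- function(data) {
  nm <- setdiff(names(data), .reserved_cols)
  nm[is_residue_key(nm)]
}

# features as a plain numeric matrix, rows preserved
feature_matrix <- function(data, cols = feature_cols(data)) {
  m <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
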