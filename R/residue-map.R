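#' Global pairwise sequence alignment
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gap penalties,
#' used to establish residue correspondence between homologous enzymes.
#' Identity is the fraction of alignment columns with identical residues;
#' similarity the fraction of columns whose substitution score is positive.
#' Both are percentages of the full alignment length, gaps included.
#'
#' A gap of length L costs `gap_open + L * gap_extend` (the Biostrings
#' convention, which performs the alignment).
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings, standard
#'   alphabet).
#' @param matrix Substitution matrix name; default `"BLOSUM62"`.
#' @param gap_open,gap_extend Affine gap penalties (positive costs); defaults
#'   10 and 0.5.
#' @param on_nonstandard What to do with non-standard residue codes:
#'   `"error"` (default) rejects them, `"X"` masks them to X.
#' @return An `alignment_result`: aligned strings with gaps, `score`,
#'   `identity_percent`, `similarity_percent`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "HEAGAWGHEE")
#' al$identity_percent   # 100
#' @export
global_align <- function(seq_a, seq_b, matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5,
                         on_nonstandard = c("error", "X")) {
  on_nonstandard <- match.arg(on_nonstandard)
  seq_a <- clean_protein_seq(seq_a, on_nonstandard, "seq_a")
  seq_b <- clean_protein_seq(seq_b, on_nonstandard, "seq_b")

  submat <- get_substitution_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  alignment_result(aligned_a, aligned_b, Biostrings::score(pa), submat)
}

alignment_result <- function(aligned_a, aligned_b, score, submat) {
  a <- strsplit(aligned_a, "")[[1]]
  b <- strsplit(aligned_b, "")[[1]]
  stopifnot(length(a) == length(b))
  len <- length(a)
  no_gap <- a != "-" & b != "-"
  identical_col <- no_gap & a == b
  positive_col <- no_gap
  positive_col[no_gap] <- submat[cbind(a[no_gap], b[no_gap])] > 0
  structure(
    list(
      aligned_a = aligned_a,
      aligned_b = aligned_b,
      length = len,
      score = as.numeric(score),
      identity_percent = 100 * sum(identical_col) / len,
      similarity_percent = 100 * sum(positive_col) / len
    ),
    class = "alignment_result"
  )
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> length ", x$length,
      ", score ", format(x$score),
      ", identity ", sprintf("%.1f%%", x$identity_percent),
      ", similarity ", sprintf("%.1f%%", x$similarity_percent), "\n", sep = "")
  invisible(x)
}

clean_protein_seq <- function(s, on_nonstandard, what) {
  if (length(s) != 1L || !nzchar(s)) {
    abort(paste0("`", what, "` must be a single non-empty sequence string."))
  }
  s <- toupper(s)
  standard <- "ACDEFGHIKLMNPQRSTVWY"
  bad <- setdiff(strsplit(s, "")[[1]], strsplit(standard, "")[[1]])
  if (length(bad) > 0) {
    if (on_nonstandard == "error") {
      abort(paste0("Non-standard residue code(s) in `", what, "`: ",
                   paste(unique(bad), collapse = ", "),
                   ". Use on_nonstandard = \"X\" to mask them."))
    }
    for (ch in unique(bad)) s <- gsub(ch, "X", s, fixed = TRUE)
  }
  s
}

get_substitution_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Pooled identity and similarity over several alignments
#'
#' The two hydrogenase subunits are aligned separately (S with S, L with L);
#' pooled identity/similarity treat the per-subunit alignments as one long
#' alignment (total identical or similar columns over total length).
#'
#' @param alignments A list of `alignment_result` objects.
#' @return A one-row tibble: `identity_percent`, `similarity_percent`,
#'   `length`, `score`.
#' @export
pool_alignments <- function(alignments) {
  stopifnot(all(purrr::map_lgl(alignments, inherits, "alignment_result")))
  len <- sum(purrr::map_dbl(alignments, "length"))
  ident <- sum(purrr::map_dbl(alignments, ~ .x$identity_percent * .x$length / 100))
  sim <- sum(purrr::map_dbl(alignments, ~ .x$similarity_percent * .x$length / 100))
  tibble(
    identity_percent = 100 * ident / len,
    similarity_percent = 100 * sim / len,
    length = len,
    score = sum(purrr::map_dbl(alignments, "score"))
  )
}

#' Build a residue correspondence map
#'
#' Turns per-subunit alignments (or an explicit correspondence table) into a
#' `residue_map`: matched alignment columns become target-reference residue
#' pairs; columns gapped in the target contribute reference-only residues
#' (zero-filled when mapping features); columns gapped in the reference
#' contribute target-only residues (dropped when mapping features).
#'
#' @param alignments Named list of `alignment_result` objects, one per
#'   subunit, with the reference sequence as `seq_a` and the target as
#'   `seq_b`; names are the subunit tags (e.g. `list(L = ..., S = ...)`).
#' @param ref_numbering,target_numbering Named lists (same names as
#'   `alignments`) of author residue numbers for each degapped sequence;
#'   default `1..n`.
#' @return A `residue_map` with tibbles `pairs` (`target`, `reference`),
#'   `reference_only`, `target_only`.
#' @examples
#' al <- global_align("HEAGAWGHEE", "HEAGAWGHEE")
#' m <- build_map(list(L = al))
#' nrow(m$pairs)  # 10, identity mapping
#' @export
build_map <- function(alignments, ref_numbering = NULL, target_numbering = NULL) {
  if (inherits(alignments, "alignment_result")) {
    alignments <- list(L = alignments)
  }
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    abort("`alignments` must be a named list (names = subunit tags).")
  }
  pairs <- list(); ref_only <- list(); tgt_only <- list()
  for (su in names(alignments)) {
    al <- alignments[[su]]
    stopifnot(inherits(al, "alignment_result"))
    a <- strsplit(al$aligned_a, "")[[1]]  # reference
    b <- strsplit(al$aligned_b, "")[[1]]  # target
    ref_n <- cumsum(a != "-")
    tgt_n <- cumsum(b != "-")
    ref_num <- ref_numbering[[su]] %||% seq_len(max(ref_n))
    tgt_num <- target_numbering[[su]] %||% seq_len(max(tgt_n))
    matched <- a != "-" & b != "-"
    pairs[[su]] <- tibble(
      target = residue_key(su, tgt_num[tgt_n[matched]]),
      reference = residue_key(su, ref_num[ref_n[matched]])
    )
    ro <- a != "-" & b == "-"
    if (any(ro)) ref_only[[su]] <- tibble(key = residue_key(su, ref_num[ref_n[ro]]))
    to <- a == "-" & b != "-"
    if (any(to)) tgt_only[[su]] <- tibble(key = residue_key(su, tgt_num[tgt_n[to]]))
  }
  new_residue_map(
    pairs = dplyr::bind_rows(pairs),
    reference_only = dplyr::bind_rows(ref_only) %||% tibble(key = character()),
    target_only = dplyr::bind_rows(tgt_only) %||% tibble(key = character())
  )
}

#' @rdname build_map
#' @param pairs Two-column data frame (`target`, `reference`) of residue
#'   keys, e.g. read with [read_pairs_file()].
#' @param reference_universe,target_universe Full residue key sets of each
#'   enzyme; unmatched keys populate the only-sets.
#' @export
build_map_from_pairs <- function(pairs, reference_universe, target_universe) {
  pairs <- as_tibble(pairs)
  if (!all(c("target", "reference") %in% names(pairs))) {
    abort("`pairs` must have columns `target` and `reference`.")
  }
  bad <- c(setdiff(pairs$reference, reference_universe),
           setdiff(pairs$target, target_universe))
  if (length(bad) > 0) {
    abort(paste0("Pair keys absent from the declared universes: ",
                 paste(unique(bad), collapse = ", ")))
  }
  new_residue_map(
    pairs = pairs[, c("target", "reference")],
    reference_only = tibble(key = setdiff(reference_universe, pairs$reference)),
    target_only = tibble(key = setdiff(target_universe, pairs$target))
  )
}

new_residue_map <- function(pairs, reference_only, target_only) {
  if (nrow(reference_only) == 0) reference_only <- tibble(key = character())
  if (nrow(target_only) == 0) target_only <- tibble(key = character())
  if (anyDuplicated(pairs$target) || anyDuplicated(pairs$reference)) {
    abort("Residue pairs must be a one-to-one matching (duplicate keys found).",
          class = "ligandpath_invalid_mapping")
  }
  if (length(intersect(pairs$reference, reference_only$key)) > 0 ||
      length(intersect(pairs$target, target_only$key)) > 0) {
    abort("Matched and unmatched residue sets overlap.",
          class = "ligandpath_invalid_mapping")
  }
  structure(
    list(pairs = as_tibble(pairs),
         reference_only = as_tibble(reference_only),
         target_only = as_tibble(target_only)),
    class = "residue_map"
  )
}

#' @export
print.residue_map <- function(x, ...) {
  cat("<residue_map> ", nrow(x$pairs), " matched pairs, ",
      nrow(x$reference_only), " reference-only, ",
      nrow(x$target_only), " target-only residues\n", sep = "")
  invisible(x)
}

reference_universe <- function(map) {
  sort_residue_keys(c(map$pairs$reference, map$reference_only$key))
}

target_universe <- function(map) {
  sort_residue_keys(c(map$pairs$target, map$target_only$key))
}

#' Map features onto the reference residue numbering
#'
#' Re-expresses a target enzyme's contact-fraction features in the reference
#' enzyme's residue universe: matched features are copied under their
#' reference keys unchanged, residues present only in the reference are
#' zero-filled, and residues present only in the target are dropped.  The
#' result always has exactly the reference universe's length, so models
#' trained on the reference enzyme can score trajectories of a homolog.
#'
#' @param x Features over the target universe: a named numeric vector, a
#'   `contact_features` object, or a feature-table data frame (metadata
#'   columns pass through).
#' @param map A `residue_map` from [build_map()] or
#'   [build_map_from_pairs()].
#' @return Features over the reference universe, same container type as the
#'   input (data frames come back as tibbles).
#' @export
map_features <- function(x, map) {
  stopifnot(inherits(map, "residue_map"))
  UseMethod("map_features")
}

#' @export
map_features.numeric <- function(x, map) {
  tgt <- target_universe(map)
  missing <- setdiff(tgt, names(x))
  extra <- setdiff(names(x), tgt)
  if (length(missing) > 0 || length(extra) > 0) {
    abort(paste0(
      "Feature keys do not match the map's target universe.",
      if (length(missing)) paste0(" Missing: ", paste(head(missing, 5), collapse = ", "), "."),
      if (length(extra)) paste0(" Not in map: ", paste(head(extra, 5), collapse = ", "), ".")
    ))
  }
  ref <- reference_universe(map)
  out <- setNames(numeric(length(ref)), ref)
  out[map$pairs$reference] <- x[map$pairs$target]
  out
}

#' @export
map_features.contact_features <- function(x, map) {
  out <- map_features(setNames(as.numeric(x), names(x)), map)
  contact_features(out,
                   n_frames_used = attr(x, "n_frames_used"),
                   escape_frame = attr(x, "escape_frame"))
}

#' @export
map_features.data.frame <- function(x, map) {
  fc <- feature_cols(x)
  meta <- x[, setdiff(names(x), fc), drop = FALSE]
  m <- feature_matrix(x, fc)
  mapped <- t(apply(m, 1L, function(row) map_features(setNames(row, fc), map)))
  if (nrow(m) == 1L) mapped <- matrix(mapped, nrow = 1L,
                                      dimnames = list(NULL, reference_universe(map)))
  dplyr::bind_cols(as_tibble(meta), as_tibble(mapped))
}

#' Read a residue correspondence table
#'
#' Two-column whitespace-separated text: target residue key, reference
#' residue key.  Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Tibble with columns `target`, `reference`.
#' @export
read_pairs_file <- function(path) {
  df <- utils::read.table(path, col.names = c("target", "reference"),
                          colClasses = "character", comment.char = "#")
  as_tibble(df)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}
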