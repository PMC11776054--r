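#' Ligand-residue contact test
#'
#' A gas molecule is in contact with a residue when the minimum distance over
#' all ligand-atom / residue-atom pairs is at or below the cutoff (4 Angstrom
#' by default).  The boundary is inclusive: a pair at exactly the cutoff
#' counts as a contact.  All atoms present in the coordinates participate; no
#' atom-type exclusions are applied.
#'
#' @param ligand_coords Numeric matrix `n x 3` of ligand atom coordinates.
#' @param residue_coords Numeric matrix `m x 3` of residue atom coordinates.
#' @param cutoff Contact distance cutoff in the coordinate units (Angstrom
#'   for real structures); default 4.0.
#' @return `TRUE` if any ligand-residue atom pair is within `cutoff`.
#' @examples
#' lig <- matrix(c(0, 0, 0), ncol = 3)
#' res <- matrix(c(4, 0, 0), ncol = 3)
#' residue_in_contact(lig, res)          # TRUE: exactly at the 4 A boundary
#' residue_in_contact(lig, res + 10)     # FALSE
#' @export
residue_in_contact <- function(ligand_coords, residue_coords, cutoff = 4.0) {
  ligand_coords <- as_coord_matrix(ligand_coords, "ligand_coords")
  residue_coords <- as_coord_matrix(residue_coords, "residue_coords")
  min_sq_dist(ligand_coords, residue_coords) <= cutoff^2
}

as_coord_matrix <- function(x, what) {
  if (is.null(dim(x)) && length(x) == 3L) x <- matrix(x, ncol = 3L)
  if (!is.matrix(x) || ncol(x) != 3L || nrow(x) < 1L) {
    abort(paste0("`", what, "` must be a non-empty n x 3 coordinate matrix."))
  }
  x
}

# squared distances between all rows of a (n x 3) and b (m x 3); min over pairs
min_sq_dist <- function(a, b) {
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  min(pmax(d2, 0))
}

# Per-frame, per-residue contact table: logical n_frames x n_residues matrix
# over the trajectory's residue universe.  Workhorse shared by escape_frame()
# and contact_fractions().
contact_table <- function(traj, cutoff = 4.0, residues = traj$residue_universe) {
  stopifnot(inherits(traj, "trajectory_record"))
  nf <- n_frames(traj)
  atom_sets <- split(seq_along(traj$enzyme_residue), traj$enzyme_residue)
  atom_sets <- atom_sets[names(atom_sets) %in% residues]
  out <- matrix(FALSE, nrow = nf, ncol = length(residues),
                dimnames = list(NULL, residues))
  static <- length(dim(traj$enzyme_xyz)) != 3L
  enz <- if (static) traj$enzyme_xyz else NULL
  c2 <- cutoff^2
  for (f in seq_len(nf)) {
    lig <- ligand_frame(traj, f)
    if (!static) enz <- enzyme_frame(traj, f)
    # squared distance of every enzyme atom to its nearest ligand atom
    d2 <- outer(rowSums(enz^2), rowSums(lig^2), "+") - 2 * tcrossprod(enz, lig)
    atom_min <- if (ncol(d2) == 1L) d2[, 1L] else do.call(pmin, asplit(d2, 2))
    for (r in names(atom_sets)) {
      if (min(atom_min[atom_sets[[r]]]) <= c2) out[f, r] <- TRUE
    }
  }
  out
}

#' Bottleneck escape frame
#'
#' Locates the end of the bound state: the ligand is considered bound while
#' it remains in contact with either of the two bottleneck residues flanking
#' the catalytic site (large-subunit residues 74 and 122 in the reference
#' enzyme).  The escape frame is one past the *last* frame of bottleneck
#' contact, so that recrossings are excluded from the retained segment.
#' Frames before it carry the bound-state signal and are discarded prior to
#' featurization, which reduces noise in the contact fractions.
#'
#' @param traj A [trajectory_record()].
#' @param bottleneck Character vector of two residue keys, default
#'   `c("L74", "L122")`.
#' @param cutoff Contact cutoff passed to the contact test; default 4.0.
#' @return Integer: the 1-based index of the first retained (post-escape)
#'   frame.  If the ligand never contacts either bottleneck residue the whole
#'   trajectory is retained and 1 is returned.  If the ligand is still in
#'   bottleneck contact at the final frame it has not escaped and an error of
#'   class `ligandpath_non_escaped` is thrown.
#' @export
escape_frame <- function(traj, bottleneck = c("L74", "L122"), cutoff = 4.0) {
  stopifnot(inherits(traj, "trajectory_record"))
  missing <- setdiff(bottleneck, traj$residue_universe)
  if (length(missing) > 0) {
    abort(paste0("Bottleneck residue(s) not in the residue universe: ",
                 paste(missing, collapse = ", ")))
  }
  present <- intersect(bottleneck, unique(traj$enzyme_residue))
  if (length(present) == 0L) return(1L)
  ct <- contact_table(traj, cutoff = cutoff, residues = present)
  any_contact <- rowSums(ct) > 0
  if (!any(any_contact)) return(1L)
  last <- max(which(any_contact))
  if (last == n_frames(traj)) {
    abort(
      "Ligand is still in bottleneck contact at the final frame (non-escaped trajectory).",
      class = "ligandpath_non_escaped"
    )
  }
  last + 1L
}

#' Per-residue contact fractions
#'
#' For each residue key in the trajectory's universe, the fraction of
#' retained frames (from `start_frame` to the last frame) in which the ligand
#' is in contact with that residue.  This is the feature vector used by the
#' pathway classifiers: one value in \[0, 1\] per residue.
#'
#' @inheritParams escape_frame
#' @param start_frame 1-based index of the first retained frame; default 1
#'   (use the whole trajectory).
#' @return A `contact_features` object: a named numeric vector over the
#'   residue universe with attributes `n_frames_used` and `escape_frame`.
#' @examples
#' sys <- build_toy_system(n_tunnels = 3, residues_per_tunnel = 2, seed = 1)
#' tr <- simulate_unbinding(sys, "T2", walker_config(seed = 7))
#' fv <- contact_fractions(tr)
#' range(fv)  # within [0, 1]
#' @export
contact_fractions <- function(traj, start_frame = 1L, cutoff = 4.0) {
  stopifnot(inherits(traj, "trajectory_record"))
  nf <- n_frames(traj)
  if (start_frame < 1L || start_frame > nf) {
    abort(paste0("`start_frame` must be in [1, ", nf, "], got ", start_frame, "."))
  }
  ct <- contact_table(traj, cutoff = cutoff)
  keep <- seq.int(start_frame, nf)
  frac <- colMeans(ct[keep, , drop = FALSE])
  contact_features(frac[traj$residue_universe],
                   n_frames_used = length(keep),
                   escape_frame = start_frame)
}

contact_features <- function(values, n_frames_used, escape_frame) {
  structure(values,
            n_frames_used = as.integer(n_frames_used),
            escape_frame = as.integer(escape_frame),
            class = "contact_features")
}

#' @export
print.contact_features <- function(x, ...) {
  nz <- sum(x > 0)
  cat("<contact_features> ", length(x), " residues (", nz, " nonzero), ",
      attr(x, "n_frames_used"), " frames from frame ",
      attr(x, "escape_frame"), "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.contact_features <- function(x, ...) {
  as_tibble(as.list(setNames(as.numeric(x), names(x))))
}

#' Featurize an unbinding trajectory
#'
#' The full featurization contract: find the bottleneck escape frame, drop
#' the bound-state segment before it, and compute per-residue contact
#' fractions over the remainder.  Equivalent to
#' `contact_fractions(traj, escape_frame(traj, bottleneck))`.  The output
#' covers the trajectory's declared residue universe, in sorted key order.
#'
#' @inheritParams escape_frame
#' @return A `contact_features` vector over the residue universe.
#' @export
featurize_trajectory <- function(traj, bottleneck = c("L74", "L122"),
                                 cutoff = 4.0) {
  start <- escape_frame(traj, bottleneck = bottleneck, cutoff = cutoff)
  contact_fractions(traj, start_frame = start, cutoff = cutoff)
}
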