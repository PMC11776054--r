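#' Trajectory records
#'
#' A `trajectory_record` holds the per-frame ligand coordinates of one
#' unbinding event together with the enzyme atoms it can contact.  Enzyme
#' coordinates may be static (one `n_atoms x 3` matrix, e.g. a rigid toy
#' enzyme or a reference frame) or per-frame (an `n_frames x n_atoms x 3`
#' array).  Every enzyme atom is assigned to exactly one residue key (see
#' [residue_key()]).
#'
#' @param ligand_xyz Numeric array `n_frames x n_ligand_atoms x 3`, or an
#'   `n_frames x 3` matrix for a single-atom ligand.
#' @param enzyme_xyz Numeric matrix `n_atoms x 3` (static enzyme) or array
#'   `n_frames x n_atoms x 3`.
#' @param enzyme_residue Character vector of residue keys, one per enzyme
#'   atom.
#' @param residue_universe Character vector of all residue keys the feature
#'   vector must cover.  Defaults to the sorted unique keys present in
#'   `enzyme_residue`.  Keys in the universe with no atoms always get
#'   contact fraction 0.
#' @param ligand Ligand species tag (e.g. `"CO"`, `"H2"`, `"O2"`).
#' @param variant Enzyme variant identifier.
#' @param label Optional true pathway label (e.g. `"T1"`).
#' @return An object of class `trajectory_record`.
#' @export
trajectory_record <- function(ligand_xyz, enzyme_xyz, enzyme_residue,
                              residue_universe = NULL,
                              ligand = "CO", variant = "ref", label = NULL) {
  if (is.matrix(ligand_xyz) && ncol(ligand_xyz) == 3) {
    ligand_xyz <- array(ligand_xyz, dim = c(nrow(ligand_xyz), 1L, 3L))
  }
  if (length(dim(ligand_xyz)) != 3L || dim(ligand_xyz)[3] != 3L) {
    abort("`ligand_xyz` must be an n_frames x n_atoms x 3 array.")
  }
  if (dim(ligand_xyz)[1] < 1L) abort("Trajectory must have at least 1 frame.")
  if (dim(ligand_xyz)[2] < 1L) abort("Ligand must have at least 1 atom.")

  per_frame_enzyme <- length(dim(enzyme_xyz)) == 3L
  if (per_frame_enzyme) {
    if (dim(enzyme_xyz)[1] != dim(ligand_xyz)[1] || dim(enzyme_xyz)[3] != 3L) {
      abort("Per-frame `enzyme_xyz` must be n_frames x n_atoms x 3.")
    }
    n_enz <- dim(enzyme_xyz)[2]
  } else {
    if (!is.matrix(enzyme_xyz) || ncol(enzyme_xyz) != 3L) {
      abort("Static `enzyme_xyz` must be an n_atoms x 3 matrix.")
    }
    n_enz <- nrow(enzyme_xyz)
  }
  if (length(enzyme_residue) != n_enz) {
    abort("`enzyme_residue` must name one residue key per enzyme atom.")
  }
  parse_residue_key(enzyme_residue)  # validates
  universe <- residue_universe %||% sort_residue_keys(unique(enzyme_residue))
  if (!all(enzyme_residue %in% universe)) {
    abort("All enzyme atoms must map to keys in `residue_universe`.")
  }

  structure(
    list(
      ligand_xyz = ligand_xyz,
      enzyme_xyz = enzyme_xyz,
      enzyme_residue = enzyme_residue,
      residue_universe = universe,
      metadata = list(ligand = ligand, variant = variant, label = label)
    ),
    class = "trajectory_record"
  )
}

#' @export
print.trajectory_record <- function(x, ...) {
  d <- dim(x$ligand_xyz)
  cat(
    "<trajectory_record> ", d[1], " frames, ", d[2], "-atom ",
    x$metadata$ligand, " ligand, ",
    length(x$enzyme_residue), " enzyme atoms in ",
    length(x$residue_universe), " residues",
    if (!is.null(x$metadata$label)) paste0(" [", x$metadata$label, "]"),
    "\n", sep = ""
  )
  invisible(x)
}

n_frames <- function(traj) dim(traj$ligand_xyz)[1]

enzyme_frame <- function(traj, f) {
  if (length(dim(traj$enzyme_xyz)) == 3L) {
    matrix(traj$enzyme_xyz[f, , ], ncol = 3L)
  } else {
    traj$enzyme_xyz
  }
}

ligand_frame <- function(traj, f) {
  matrix(traj$ligand_xyz[f, , ], ncol = 3L)
}
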