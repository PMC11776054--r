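#' Read / write feature tables
#'
#' A feature table has one row per trajectory: metadata columns (`label`,
#' `ligand`, `variant`) followed by one contact-fraction column per residue
#' key, ordered by sorted (subunit, position).  `write_feature_table()`
#' enforces that canonical column order.
#'
#' @param data Feature table.
#' @param path CSV or TSV file path (delimiter chosen from the extension).
#' @return `read_feature_table()` a tibble; `write_feature_table()` the
#'   path, invisibly.
#' @export
write_feature_table <- function(data, path) {
  data <- as_tibble(data)
  fc <- sort_residue_keys(feature_cols(data))
  meta <- intersect(.reserved_cols, names(data))
  out <- data[, c(meta, fc), drop = FALSE]
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path)
  else readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- if (grepl("\\.tsv$", path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  fc <- feature_cols(df)
  if (length(fc) == 0) {
    abort("No residue-key feature columns found in the table.")
  }
  bad <- fc[purrr::map_lgl(df[fc], ~ any(.x < 0 | .x > 1, na.rm = TRUE))]
  if (length(bad) > 0) {
    abort(paste0("Contact fractions outside [0, 1] in column(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  df
}

#' Read an MD trajectory into a trajectory record
#'
#' Thin wrapper over bio3d: a PDB topology assigns each atom to a chain and
#' author residue number (the residue key), and a DCD (or multi-model PDB)
#' supplies per-frame coordinates.  The ligand is selected by residue name.
#'
#' @param topology Path to a PDB file describing the system.
#' @param trajectory Optional path to a DCD trajectory; if `NULL`, the
#'   topology's own (possibly multi-model) coordinates are used.
#' @param ligand_resname Residue name(s) identifying the ligand atoms, e.g.
#'   `"CMO"` for carbon monoxide.
#' @param ligand Ligand species tag stored in the record metadata.
#' @param variant Enzyme variant tag.
#' @return A [trajectory_record()].
#' @export
read_trajectory <- function(topology, trajectory = NULL,
                            ligand_resname, ligand = ligand_resname,
                            variant = "ref") {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("Reading PDB/DCD files requires the bio3d package.")
  }
  pdb <- bio3d::read.pdb(topology, multi = TRUE)
  at <- pdb$atom
  is_lig <- at$resid %in% ligand_resname
  if (!any(is_lig)) {
    abort(paste0("No atoms with residue name ", paste(ligand_resname, collapse = "/"),
                 " in the topology."))
  }
  xyz <- if (is.null(trajectory)) pdb$xyz else bio3d::read.dcd(trajectory)
  xyz <- as.matrix(xyz)
  nf <- nrow(xyz)
  coords <- array(xyz, dim = c(nf, 3, ncol(xyz) / 3))
  coords <- aperm(coords, c(1, 3, 2))  # frames x atoms x 3

  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "L"
  keys <- residue_key(chain[!is_lig], at$resno[!is_lig])

  trajectory_record(
    ligand_xyz = coords[, which(is_lig), , drop = FALSE],
    enzyme_xyz = coords[, which(!is_lig), , drop = FALSE],
    enzyme_residue = keys,
    ligand = ligand, variant = variant
  )
}

#' Write a trajectory as a multi-model PDB
#'
#' Serializes a trajectory record (ligand + enzyme atoms) as a multi-model
#' PDB file, one MODEL per frame, readable with `bio3d::read.pdb(multi =
#' TRUE)` for round-trip testing.  Subunit tags become chain identifiers
#' (ligand atoms are chain `X`, residue name `LIG`).
#'
#' @param traj A [trajectory_record()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_record"))
  nf <- n_frames(traj)
  n_lig <- dim(traj$ligand_xyz)[2]
  keys <- parse_residue_key(traj$enzyme_residue)

  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    lig <- ligand_frame(traj, f)
    enz <- enzyme_frame(traj, f)
    serial <- 0L
    for (a in seq_len(n_lig)) {
      serial <- serial + 1L
      writeLines(pdb_atom_line(serial, "C", "LIG", "X", 1L, lig[a, ]), con)
    }
    for (a in seq_len(nrow(enz))) {
      serial <- serial + 1L
      writeLines(pdb_atom_line(serial, "C", "GLY",
                               substr(keys$subunit[a], 1, 1),
                               keys$position[a], enz[a, ]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB fixed-width ATOM record: name cols 13-16, resName 18-20, chainID 22,
# resSeq 23-26, x/y/z 31-54
pdb_atom_line <- function(serial, name, resname, chain, resno, xyz) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, resname, chain, resno, xyz[1], xyz[2], xyz[3])
}
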