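# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (exhaustive enumeration, textbook DP) and
# share no code with the package internals.

# exhaustive atom-pair contact scan
oracle_in_contact <- function(lig, res, cutoff = 4.0) {
  for (i in seq_len(nrow(lig))) {
    for (j in seq_len(nrow(res))) {
      if (sqrt(sum((lig[i, ] - res[j, ])^2)) <= cutoff) return(TRUE)
    }
  }
  FALSE
}

# per-frame, per-residue contact table by exhaustive scan
oracle_contact_table <- function(traj, cutoff = 4.0) {
  nf <- dim(traj$ligand_xyz)[1]
  residues <- traj$residue_universe
  static <- length(dim(traj$enzyme_xyz)) != 3L
  out <- matrix(FALSE, nf, length(residues), dimnames = list(NULL, residues))
  for (f in seq_len(nf)) {
    lig <- matrix(traj$ligand_xyz[f, , ], ncol = 3)
    enz <- if (static) traj$enzyme_xyz else matrix(traj$enzyme_xyz[f, , ], ncol = 3)
    for (r in residues) {
      idx <- which(traj$enzyme_residue == r)
      if (length(idx) > 0 &&
          oracle_in_contact(lig, enz[idx, , drop = FALSE], cutoff)) {
        out[f, r] <- TRUE
      }
    }
  }
  out
}

# textbook Needleman-Wunsch with affine gaps (Gotoh); a gap of length L
# costs open + L * ext, matching the documented alignment convention
oracle_nw_score <- function(a, b, S, open = 10, ext = 0.5) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in seq_len(m) + 1) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
        S[a[i - 1], b[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# AUC as the exhaustive Mann-Whitney pair statistic (ties count 1/2)
oracle_auc <- function(truth, score, positive) {
  pos <- score[truth == positive]
  neg <- score[truth != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# direct arithmetic on a plain count matrix (rows = truth)
oracle_ba <- function(counts) {
  rs <- rowSums(counts)
  mean((diag(counts) / rs)[rs > 0])
}

oracle_mcc <- function(counts) {
  s <- sum(counts); c_ <- sum(diag(counts))
  t_k <- rowSums(counts); p_k <- colSums(counts)
  den <- sqrt((s^2 - sum(p_k^2)) * (s^2 - sum(t_k^2)))
  if (den == 0) return(0)
  (c_ * s - sum(t_k * p_k)) / den
}

# tiny scripted trajectory: single-atom ligand moving along x, residues
# placed on the x axis at given positions (one atom each)
make_line_traj <- function(ligand_x, residue_x, keys = NULL, label = "T1") {
  keys <- keys %||% paste0("L", seq_along(residue_x))
  trajectory_record(
    ligand_xyz = cbind(ligand_x, 0, 0),
    enzyme_xyz = cbind(residue_x, 0, 0),
    enzyme_residue = keys,
    label = label
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random trajectory for property tests
random_traj <- function(seed, n_frames = 6, n_res = 5, n_lig = 2) {
  withr::with_seed(seed, {
    trajectory_record(
      ligand_xyz = array(runif(n_frames * n_lig * 3, -6, 6),
                         dim = c(n_frames, n_lig, 3)),
      enzyme_xyz = matrix(runif(n_res * 2 * 3, -6, 6), ncol = 3),
      enzyme_residue = rep(paste0("L", seq_len(n_res)), each = 2)
    )
  })
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}
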