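#' Build a radial multi-tunnel toy enzyme
#'
#' Constructs a simplified enzyme geometry for generating labeled unbinding
#' trajectories: `n_tunnels` escape routes radiate from a common catalytic
#' center at maximally separated directions on the sphere (a Fibonacci
#' lattice), each lined with `residues_per_tunnel` residues at regular radial
#' spacing.  A shared core shell of residues sits one spacing step from the
#' center, including the two designated bottleneck residues (`L74`, `L122`)
#' that flank the catalytic site, so that every trajectory carries the same
#' bound-state signal regardless of its escape route -- mirroring real
#' tunnel networks where the primary routes share the initial segment of the
#' unbinding path.
#'
#' Tunnel residues of tunnel `k` get keys `S(100*k + j)`; core residues are
#' `L74`, `L122` and `L1..L6`.  Each residue is realized as 3 atoms jittered
#' around its center so any-atom contact logic is exercised.
#'
#' @param n_tunnels Number of escape tunnels (labels `T1..Tn`); default 9.
#' @param residues_per_tunnel Residues lining each tunnel; default 5.
#' @param seed Integer seed controlling atom jitter; geometry is
#'   deterministic for a fixed seed.
#' @param spacing Radial distance between consecutive tunnel residues
#'   (length units; 3.0 by default, commensurate with the 4.0 contact
#'   cutoff so a ligand walking along the axis stays in contact with
#'   successive residues).
#' @param first_radius Radius of the innermost tunnel residue; default 7.0,
#'   which keeps tunnels contact-disjoint (nearest approach of a tunnel axis
#'   to another tunnel's residues stays above cutoff + atom jitter) for up
#'   to ~12 tunnels (minimum inter-axis angle 53 degrees).
#' @return A `toy_tunnel_system`: residue table (key, tunnel, center, atoms),
#'   tunnel axes, tunnel labels, bottleneck keys, and the residue universe.
#' @examples
#' sys <- build_toy_system(n_tunnels = 9, residues_per_tunnel = 5, seed = 1)
#' sys
#' @export
build_toy_system <- function(n_tunnels = 9, residues_per_tunnel = 5, seed = 1,
                             spacing = 3.0, first_radius = 7.0) {
  if (n_tunnels < 2) {
    abort("`n_tunnels` must be >= 2: a single route cannot define a classification problem.",
          class = "ligandpath_invalid_geometry")
  }
  if (residues_per_tunnel < 1) {
    abort("`residues_per_tunnel` must be >= 1.",
          class = "ligandpath_invalid_geometry")
  }

  axes <- fibonacci_sphere(n_tunnels)
  labels <- paste0("T", seq_len(n_tunnels))
  rownames(axes) <- labels

  # core shell: bottleneck pair plus 6 residues, all one spacing step out
  core_dirs <- rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
    c(0, 0, 1), c(0, 0, -1),
    c(1, 1, 1) / sqrt(3), c(-1, -1, -1) / sqrt(3)
  )
  core_keys <- c("L74", "L122", paste0("L", 1:6))
  core_centers <- core_dirs * spacing

  tun <- expand.grid(j = seq_len(residues_per_tunnel), k = seq_len(n_tunnels))
  tun_keys <- residue_key("S", 100L * tun$k + tun$j)
  tun_radius <- first_radius + (tun$j - 1) * spacing
  tun_centers <- axes[tun$k, , drop = FALSE] * tun_radius

  residues <- tibble(
    key = c(core_keys, tun_keys),
    tunnel = c(rep("core", length(core_keys)), labels[tun$k]),
    x = c(core_centers[, 1], tun_centers[, 1]),
    y = c(core_centers[, 2], tun_centers[, 2]),
    z = c(core_centers[, 3], tun_centers[, 3])
  )
  stopifnot(!anyDuplicated(residues$key))

  # 3 atoms per residue, jittered around the center (sd 0.35 length units)
  atoms <- withr::with_seed(seed, {
    n_atoms <- 3L
    jitter <- matrix(rnorm(nrow(residues) * n_atoms * 3, sd = 0.35), ncol = 3)
    tibble(
      key = rep(residues$key, each = n_atoms),
      x = rep(residues$x, each = n_atoms) + jitter[, 1],
      y = rep(residues$y, each = n_atoms) + jitter[, 2],
      z = rep(residues$z, each = n_atoms) + jitter[, 3]
    )
  })

  structure(
    list(
      n_tunnels = as.integer(n_tunnels),
      residues_per_tunnel = as.integer(residues_per_tunnel),
      spacing = spacing,
      first_radius = first_radius,
      tunnel_labels = labels,
      tunnel_axes = axes,
      bottleneck = c("L74", "L122"),
      residues = residues,
      atoms = atoms,
      residue_universe = sort_residue_keys(unique(residues$key)),
      seed = as.integer(seed)
    ),
    class = "toy_tunnel_system"
  )
}

#' @export
print.toy_tunnel_system <- function(x, ...) {
  cat("<toy_tunnel_system> ", x$n_tunnels, " tunnels x ",
      x$residues_per_tunnel, " residues + ",
      sum(x$residues$tunnel == "core"), " core residues (",
      length(x$residue_universe), " keys, bottleneck ",
      paste(x$bottleneck, collapse = "/"), ")\n", sep = "")
  invisible(x)
}

# n points well spread on the unit sphere (deterministic Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Walker configuration for synthetic unbinding
#'
#' Parameters of the biased random walk that emulates a gas molecule leaving
#' the toy enzyme.  The defaults define the reference study conditions of
#' the synthetic benchmark: a short bound-state dwell at the bottleneck,
#' low-noise outward motion, and occasional roaming between tunnels (real
#' ligands can roam through the tunnel network before escaping, which is
#' what makes pathway assignment nontrivial).
#'
#' @param step_size Radial advance per frame (length units); default 1.5.
#' @param noise_sigma Isotropic Gaussian positional noise per frame; default
#'   0.2 (about 13% of the step).
#' @param roam_probability Per-frame probability of starting a temporary
#'   excursion toward another tunnel; default 0.05.
#' @param roam_frames Mean length (frames) of a roaming excursion; default 4.
#' @param dwell_frames Frames spent near the bottleneck before the outward
#'   walk; default 10.
#' @param n_frames_max Hard cap on trajectory length; exceeding it without
#'   escaping raises a non-escaped error.  Default 500.
#' @param bond_length Ligand is a rigid diatomic; distance between its two
#'   atoms (0.11 length units, a CO/H2/O2-like scale).
#' @param seed Integer seed.
#' @return A `walker_config` list.
#' @export
walker_config <- function(step_size = 1.5, noise_sigma = 0.2,
                          roam_probability = 0.05, roam_frames = 4,
                          dwell_frames = 10, n_frames_max = 500,
                          bond_length = 0.11, seed = 1) {
  if (step_size <= 0) abort("`step_size` must be > 0.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (roam_probability < 0 || roam_probability > 1) {
    abort("`roam_probability` must be in [0, 1].")
  }
  if (dwell_frames < 0) abort("`dwell_frames` must be >= 0.")
  structure(
    list(step_size = step_size, noise_sigma = noise_sigma,
         roam_probability = roam_probability, roam_frames = roam_frames,
         dwell_frames = as.integer(dwell_frames),
         n_frames_max = as.integer(n_frames_max),
         bond_length = bond_length, seed = as.integer(seed)),
    class = "walker_config"
  )
}

#' Simulate one unbinding trajectory
#'
#' The ligand (a rigid diatomic) starts at the catalytic center, dwells near
#' the bottleneck residues for `dwell_frames` frames, then performs a biased
#' random walk outward along the axis of the designated tunnel with Gaussian
#' noise.  With probability `roam_probability` per frame it starts an
#' excursion toward a different tunnel's axis (geometric duration, mean
#' `roam_frames`) before resuming its true route, producing the
#' mixed-tunnel contact signatures seen when ligands roam through the
#' tunnel network.  The walk ends when the ligand passes beyond the
#' outermost residue of its tunnel plus the contact cutoff.
#'
#' @param system A [build_toy_system()] geometry.
#' @param true_label Tunnel id to escape through, e.g. `"T3"`.
#' @param config A [walker_config()].
#' @return A [trajectory_record()] with the true label in its metadata.
#'   Deterministic for a fixed `config$seed`.
#' @export
simulate_unbinding <- function(system, true_label, config = walker_config()) {
  stopifnot(inherits(system, "toy_tunnel_system"))
  if (!true_label %in% system$tunnel_labels) {
    abort(paste0("`true_label` must be one of ", paste(system$tunnel_labels, collapse = ", "),
                 "; got \"", true_label, "\"."))
  }
  stopifnot(inherits(config, "walker_config"))

  axis_true <- system$tunnel_axes[true_label, ]
  escape_radius <- system$first_radius +
    (system$residues_per_tunnel - 1) * system$spacing + 4.0 + config$step_size

  centers <- withr::with_seed(config$seed, {
    pos <- c(0, 0, 0)
    frames <- list()
    # bound-state dwell: small jitter around the catalytic center
    for (f in seq_len(config$dwell_frames)) {
      pos <- c(0, 0, 0) + rnorm(3, sd = config$noise_sigma)
      frames[[length(frames) + 1L]] <- pos
    }
    r <- 0
    roaming_left <- 0L
    active_axis <- axis_true
    repeat {
      if (length(frames) >= config$n_frames_max) {
        abort(paste0("Walk exceeded n_frames_max = ", config$n_frames_max,
                     " without escaping."),
              class = "ligandpath_non_escaped")
      }
      if (roaming_left > 0L) {
        roaming_left <- roaming_left - 1L
      } else if (config$roam_probability > 0 &&
                 runif(1) < config$roam_probability) {
        other <- setdiff(system$tunnel_labels, true_label)
        active_axis <- system$tunnel_axes[sample(other, 1L), ]
        roaming_left <- stats::rgeom(1L, prob = 1 / config$roam_frames)
      } else {
        active_axis <- axis_true
      }
      r <- r + config$step_size
      target <- active_axis * r
      pos <- target + rnorm(3, sd = config$noise_sigma)
      frames[[length(frames) + 1L]] <- pos
      # escape requires leaving along the labeled tunnel, not a roam excursion
      if (identical(active_axis, axis_true) && r >= escape_radius &&
          sqrt(sum(pos^2)) >= escape_radius) break
    }
    do.call(rbind, frames)
  })

  # rigid diatomic: second atom offset along the instantaneous direction
  nf <- nrow(centers)
  lig <- array(0, dim = c(nf, 2L, 3L))
  dirs <- centers / pmax(sqrt(rowSums(centers^2)), 1e-8)
  lig[, 1L, ] <- centers
  lig[, 2L, ] <- centers + dirs * config$bond_length

  trajectory_record(
    ligand_xyz = lig,
    enzyme_xyz = as.matrix(system$atoms[, c("x", "y", "z")]),
    enzyme_residue = system$atoms$key,
    residue_universe = system$residue_universe,
    ligand = "CO", variant = "toy",
    label = true_label
  )
}

#' Generate a labeled synthetic dataset
#'
#' Draws trajectory labels from a multinomial over `class_weights`, simulates
#' each unbinding event, featurizes it (bottleneck truncation + contact
#' fractions), and assembles the feature table.  The default weights are
#' heavily imbalanced in favor of the primary tunnels (T1, T2, T7), the
#' regime the classifiers are designed for.
#'
#' @param system A [build_toy_system()].
#' @param n_trajectories Number of trajectories to generate.
#' @param class_weights Named numeric vector of label probabilities summing
#'   to 1; names must be tunnel labels of `system`.  Default: an imbalanced
#'   distribution over all tunnels with T1/T2/T7 carrying ~72% of the mass
#'   (weights for tunnels beyond the system's count are dropped and the
#'   remainder renormalized).
#' @param config A [walker_config()]; its seed drives label sampling and all
#'   per-trajectory walks.
#' @param cutoff Contact cutoff used in featurization; default 4.0.
#' @return A tibble: `label`, `ligand`, `variant` columns plus one contact
#'   fraction column per residue key (sorted key order).
#' @examples
#' sys <- build_toy_system(n_tunnels = 3, residues_per_tunnel = 2, seed = 1)
#' ds <- generate_dataset(sys, 12, config = walker_config(seed = 1))
#' dplyr::count(ds, label)
#' @export
generate_dataset <- function(system, n_trajectories,
                             class_weights = default_class_weights(system),
                             config = walker_config(), cutoff = 4.0) {
  stopifnot(inherits(system, "toy_tunnel_system"))
  if (is.null(names(class_weights)) ||
      !all(names(class_weights) %in% system$tunnel_labels)) {
    abort("`class_weights` must be named by tunnel labels of the system.")
  }
  if (abs(sum(class_weights) - 1) > 1e-8) {
    abort("`class_weights` must sum to 1.")
  }
  n_active <- sum(class_weights > 0)
  if (n_trajectories < n_active) {
    warn(paste0("n_trajectories (", n_trajectories, ") is smaller than the number of ",
                "classes with nonzero weight (", n_active, "); some classes will be absent."))
  }

  labels <- withr::with_seed(config$seed, {
    sample(names(class_weights), size = n_trajectories, replace = TRUE,
           prob = class_weights)
  })
  # per-trajectory seeds derived deterministically from the config seed
  traj_seeds <- withr::with_seed(config$seed,
                                 sample.int(.Machine$integer.max, n_trajectories))

  rows <- purrr::map2(labels, traj_seeds, function(lab, s) {
    cfg <- config
    cfg$seed <- s
    tr <- simulate_unbinding(system, lab, cfg)
    fv <- featurize_trajectory(tr, bottleneck = system$bottleneck, cutoff = cutoff)
    as_tibble(fv)
  })

  dplyr::bind_cols(
    tibble(label = labels, ligand = "CO", variant = "toy"),
    dplyr::bind_rows(rows)
  )
}

#' @rdname generate_dataset
#' @export
default_class_weights <- function(system) {
  base <- c(T1 = 0.35, T2 = 0.25, T3 = 0.06, T4 = 0.05, T5 = 0.04,
            T6 = 0.04, T7 = 0.12, T8 = 0.05, T9 = 0.04)
  w <- base[names(base) %in% system$tunnel_labels]
  if (length(w) < system$n_tunnels) {
    extra <- setdiff(system$tunnel_labels, names(w))
    w <- c(w, setNames(rep(0.02, length(extra)), extra))
  }
  w / sum(w)
}
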