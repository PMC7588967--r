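# Seeded generators that emulate the statistical structure of the study's
# inputs — 200-frame/200-ns trajectories in triplicate, per-frame MM-PBSA
# tables, and docking pose clouds — so every analysis stage is testable
# without MD, docking, or structure downloads. Trajectories are
# rigid-receptor/jittering-ligand: internal protein dynamics are irrelevant
# to the statistics implemented here.

#' Settings for the synthetic generators
#'
#' Defaults mirror the study conditions: 200 frames at 1 ns per frame,
#' triplicate runs, energy-term means at the worked decomposition example
#' (VDWAALS -40, ENPOLAR -5, EEL -30, EPB +60 kcal/mol), and component
#' standard deviations (10, 2) so that the packing term dominates the
#' variance of the total.
#'
#' @param seed integer seed; every generator is deterministic given the
#'   spec (vary the seed for replicates).
#' @param n_frames frames per trajectory.
#' @param frame_interval_ns snapshot spacing (ns).
#' @param jitter_sigma_A isotropic per-atom Gaussian jitter of the bound
#'   ligand (Angstrom).
#' @param exit_frame 0-based frame at which an unbinding ligand starts
#'   drifting, or `NULL` for a bound trajectory.
#' @param drift_rate_A_per_frame post-exit drift speed (Angstrom/frame,
#'   > 0 for unbinding).
#' @param energy_means named 4-vector of term means
#'   (VDWAALS, ENPOLAR, EEL, EPB), kcal/mol.
#' @param energy_sds length-2 vector: standard deviations of dG_vdw and
#'   dG_ele (kcal/mol).
#' @param target_corr_vdw_total,target_corr_ele_total optional target
#'   correlations of each component with the total; `NULL` draws the two
#'   components independently.
#' @param pose_sigma_A isotropic spread of patch-bound pose clouds.
#' @param pose_weights simplex over (front, back, other).
#' @param n_poses number of poses to generate.
#' @param n_replicates replicate trajectories per complex.
#' @return list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L, n_frames = 200L, frame_interval_ns = 1,
                           jitter_sigma_A = 0.5, exit_frame = NULL,
                           drift_rate_A_per_frame = 1,
                           energy_means = c(VDWAALS = -40, ENPOLAR = -5,
                                            EEL = -30, EPB = 60),
                           energy_sds = c(10, 2),
                           target_corr_vdw_total = NULL,
                           target_corr_ele_total = NULL,
                           pose_sigma_A = 2,
                           pose_weights = c(front = 0.01, back = 0.98,
                                            other = 0.01),
                           n_poses = 200L, n_replicates = 3L) {
  stopifnot(n_frames >= 1L, frame_interval_ns > 0, jitter_sigma_A >= 0,
            all(energy_sds >= 0), length(energy_sds) == 2L,
            all(pose_weights >= 0), abs(sum(pose_weights) - 1) < 1e-9,
            pose_sigma_A > 0, n_poses >= 1L, n_replicates >= 1L)
  if (!is.null(target_corr_vdw_total)) {
    stopifnot(abs(target_corr_vdw_total) < 1, abs(target_corr_ele_total) < 1)
  }
  structure(list(
    seed = as.integer(seed), n_frames = as.integer(n_frames),
    frame_interval_ns = frame_interval_ns, jitter_sigma_A = jitter_sigma_A,
    exit_frame = if (is.null(exit_frame)) NULL else as.integer(exit_frame),
    drift_rate_A_per_frame = drift_rate_A_per_frame,
    energy_means = energy_means, energy_sds = energy_sds,
    target_corr_vdw_total = target_corr_vdw_total,
    target_corr_ele_total = target_corr_ele_total,
    pose_sigma_A = pose_sigma_A, pose_weights = pose_weights,
    n_poses = as.integer(n_poses), n_replicates = as.integer(n_replicates)
  ), class = "synthetic_spec")
}

#' Build a toy receptor-ligand complex
#'
#' Receptor atoms sit on a jittered cubic lattice (1.5 A spacing); the
#' ligand is a short chain placed 3 A from the first receptor atom, which
#' guarantees at least one heavy-atom cross pair within 7 A at frame 0.
#' Deterministic given the seed.
#'
#' @param n_receptor_atoms,n_ligand_atoms atom counts (>= 1).
#' @param seed integer seed.
#' @param with_phosphorus put a phosphorus atom at the head of the ligand
#'   (for patch-classifier reference points).
#' @return list of class `"toy_complex"`: `structure` (a [Structure] with
#'   receptor chain A and ligand chain B), `receptor_atoms`, `ligand_atoms`
#'   index vectors.
#' @export
make_toy_complex <- function(n_receptor_atoms, n_ligand_atoms, seed = 1L,
                             with_phosphorus = FALSE) {
  stopifnot(n_receptor_atoms >= 1L, n_ligand_atoms >= 1L)
  set.seed(seed)
  side <- ceiling(n_receptor_atoms^(1 / 3))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  rec <- 1.5 * as.matrix(grid[seq_len(n_receptor_atoms), ]) +
    matrix(stats::rnorm(3L * n_receptor_atoms, sd = 0.1),
           ncol = 3L)
  anchor <- rec[1L, ]
  lig <- t(vapply(seq_len(n_ligand_atoms), function(i) {
    anchor + c(3 + 1.4 * (i - 1L), 0, 0)
  }, numeric(3)))
  lig <- lig + matrix(stats::rnorm(3L * n_ligand_atoms, sd = 0.05), ncol = 3L)
  n <- n_receptor_atoms + n_ligand_atoms
  lig_elem <- rep("C", n_ligand_atoms)
  lig_name <- paste0("C", seq_len(n_ligand_atoms))
  if (with_phosphorus) {
    lig_elem[1L] <- "P"
    lig_name[1L] <- "P1"
  }
  st <- Structure(data.frame(
    serial = seq_len(n),
    name = c(paste0("C", seq_len(n_receptor_atoms)), lig_name),
    element = c(rep("C", n_receptor_atoms), lig_elem),
    resname = c(rep("REC", n_receptor_atoms), rep("LIG", n_ligand_atoms)),
    resid = c(seq_len(n_receptor_atoms), rep(1L, n_ligand_atoms)),
    chain = c(rep("A", n_receptor_atoms), rep("B", n_ligand_atoms)),
    x = c(rec[, 1L], lig[, 1L]),
    y = c(rec[, 2L], lig[, 2L]),
    z = c(rec[, 3L], lig[, 3L]),
    stringsAsFactors = FALSE
  ))
  structure(list(structure = st,
                 receptor_atoms = seq_len(n_receptor_atoms),
                 ligand_atoms = n_receptor_atoms + seq_len(n_ligand_atoms)),
            class = "toy_complex")
}

.jittered_frames <- function(cplx, spec) {
  base <- coords(cplx$structure)
  lig <- cplx$ligand_atoms
  frames <- vector("list", spec$n_frames)
  frames[[1L]] <- base
  for (i in seq_len(spec$n_frames)[-1L]) {
    f <- base
    if (spec$jitter_sigma_A > 0) {
      f[lig, ] <- f[lig, , drop = FALSE] +
        matrix(stats::rnorm(3L * length(lig), sd = spec$jitter_sigma_A),
               ncol = 3L)
    }
    frames[[i]] <- f
  }
  frames
}

#' Simulate a stably bound trajectory
#'
#' Receptor fixed; each ligand atom is redrawn every frame as its initial
#' position plus isotropic Gaussian jitter. Frame 0 is exactly the initial
#' structure.
#'
#' @param cplx a [make_toy_complex()] result.
#' @param spec a [synthetic_spec()] with `exit_frame = NULL`.
#' @return a [Trajectory].
#' @export
simulate_bound_trajectory <- function(cplx, spec) {
  stopifnot(inherits(cplx, "toy_complex"), inherits(spec, "synthetic_spec"))
  if (!is.null(spec$exit_frame)) {
    stop("bound trajectory requires exit_frame = NULL")
  }
  set.seed(spec$seed)
  Trajectory(cplx$structure, .jittered_frames(cplx, spec),
             spec$frame_interval_ns)
}

#' Simulate an unbinding trajectory
#'
#' Bound behaviour until `exit_frame`; afterwards the whole ligand is
#' additionally translated by `drift_rate x (frame - exit_frame)` along a
#' fixed random unit vector, emulating a ligand leaving the binding pocket.
#'
#' @param cplx a [make_toy_complex()] result.
#' @param spec a [synthetic_spec()] with `exit_frame < n_frames` and
#'   `drift_rate_A_per_frame > 0`.
#' @return a [Trajectory].
#' @export
simulate_unbinding_trajectory <- function(cplx, spec) {
  stopifnot(inherits(cplx, "toy_complex"), inherits(spec, "synthetic_spec"))
  if (is.null(spec$exit_frame) || spec$exit_frame >= spec$n_frames) {
    stop("unbinding trajectory requires exit_frame < n_frames")
  }
  if (spec$drift_rate_A_per_frame <= 0) {
    stop("drift_rate_A_per_frame must be > 0")
  }
  set.seed(spec$seed)
  dir <- stats::rnorm(3L)
  dir <- dir / sqrt(sum(dir^2))
  frames <- .jittered_frames(cplx, spec)
  lig <- cplx$ligand_atoms
  for (i in seq_along(frames)) {
    f0 <- i - 1L  # 0-based frame index
    if (f0 >= spec$exit_frame) {
      shift <- spec$drift_rate_A_per_frame * (f0 - spec$exit_frame)
      frames[[i]][lig, ] <- frames[[i]][lig, , drop = FALSE] +
        matrix(dir * shift, nrow = length(lig), ncol = 3L, byrow = TRUE)
    }
  }
  Trajectory(cplx$structure, frames, spec$frame_interval_ns)
}

# Solve the bivariate covariance of (dG_vdw, dG_ele) implied by target
# correlations of each component with their sum; independent components
# when no targets are given. One free covariance serves two targets, so
# the closed form sets the total sd to r_vt*sv + r_et*se (their exact sum
# constraint); mutually consistent targets — (r_vt*sv)^2 - (r_et*se)^2 =
# sv^2 - se^2 — are then matched exactly, inconsistent ones to first
# order with the discrepancy split between the components.
.energy_covariance <- function(spec) {
  sv <- spec$energy_sds[1L]
  se <- spec$energy_sds[2L]
  if (is.null(spec$target_corr_vdw_total)) {
    return(matrix(c(sv^2, 0, 0, se^2), 2L))
  }
  st <- spec$target_corr_vdw_total * sv + spec$target_corr_ele_total * se
  cov_ve <- (st^2 - sv^2 - se^2) / 2
  S <- matrix(c(sv^2, cov_ve, cov_ve, se^2), 2L)
  if (det(S) <= 0) {
    stop("infeasible correlation targets: implied covariance determinant ",
         format(det(S)))
  }
  S
}

#' Simulate a per-frame MM-PBSA energy table
#'
#' Draws (dG_vdw, dG_ele) per frame from a bivariate normal (means from the
#' sums of `energy_means`, covariance from `energy_sds` and the optional
#' correlation targets), then back-fills the four parsed terms by fixed
#' splits — VDWAALS:ENPOLAR = 9:1 and EEL = dG_ele/2 - 45,
#' EPB = dG_ele/2 + 45 (sign-opposed, reproducing the worked decomposition
#' example at the default means) — so that parsing and decomposition
#' round-trip the drawn sums exactly.
#'
#' @param spec a [synthetic_spec()].
#' @return an [EnergySeries] of `n_frames` records.
#' @export
simulate_energy_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  mu <- c(spec$energy_means[["VDWAALS"]] + spec$energy_means[["ENPOLAR"]],
          spec$energy_means[["EEL"]] + spec$energy_means[["EPB"]])
  S <- .energy_covariance(spec)
  draws <- MASS::mvrnorm(spec$n_frames, mu = mu, Sigma = S)
  if (spec$n_frames == 1L) draws <- matrix(draws, nrow = 1L)
  dG_vdw <- draws[, 1L]
  dG_ele <- draws[, 2L]
  EnergySeries(data.frame(
    frame = seq_len(spec$n_frames) - 1L,
    VDWAALS = 0.9 * dG_vdw,
    EEL = dG_ele / 2 - 45,
    EPB = dG_ele / 2 + 45,
    ENPOLAR = 0.1 * dG_vdw
  ))
}

#' Simulate a docking pose set around patch centroids
#'
#' Pose counts per label follow `pose_weights` deterministically (largest
#' remainder), so generated frequencies reproduce the weights exactly at
#' the reporting precision; label order is then shuffled. Front/back poses
#' put a phosphorus-headed 3-atom fragment with its reference point drawn
#' from an isotropic Gaussian around the patch centroid, truncated at 4
#' standard deviations so a generated patch pose always lies within its
#' own motif region; "other" poses are drawn uniformly in the region
#' 15-30 A away from both centroids.
#' Scores are strictly decreasing with file order.
#'
#' @param receptor a [Structure] (carried into the [PoseSet]).
#' @param front_centroid,back_centroid length-3 patch centroids, at least
#'   `4 * pose_sigma_A` apart (separability guard).
#' @param spec a [synthetic_spec()].
#' @return a [PoseSet] of `n_poses` poses.
#' @export
simulate_pose_set <- function(receptor, front_centroid, back_centroid, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sep <- sqrt(sum((front_centroid - back_centroid)^2))
  if (sep < 4 * spec$pose_sigma_A) {
    stop("patch centroids must be at least 4 x pose_sigma_A apart (",
         format(sep, digits = 3), " A < ",
         format(4 * spec$pose_sigma_A, digits = 3), " A)")
  }
  set.seed(spec$seed)
  n <- spec$n_poses
  w <- spec$pose_weights[c("front", "back", "other")]
  base <- floor(w * n)
  rem <- w * n - base
  short <- n - sum(base)
  if (short > 0L) {
    base[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      base[order(rem, decreasing = TRUE)[seq_len(short)]] + 1L
  }
  labels <- sample(rep(c("front", "back", "other"), times = base))
  draw_other <- function() {
    mid <- (front_centroid + back_centroid) / 2
    for (k in seq_len(10000L)) {
      u <- stats::rnorm(3L)
      u <- u / sqrt(sum(u^2))
      p <- mid + u * stats::runif(1L, 0, 30)
      df <- sqrt(sum((p - front_centroid)^2))
      db <- sqrt(sum((p - back_centroid)^2))
      if (df >= 15 && df <= 30 && db >= 15 && db <= 30) return(p)
    }
    stop("could not place an 'other' pose 15-30 A from both centroids")
  }
  draw_patch <- function(centroid) {
    repeat {
      off <- stats::rnorm(3L, sd = spec$pose_sigma_A)
      if (sqrt(sum(off^2)) <= 4 * spec$pose_sigma_A) return(centroid + off)
    }
  }
  pose_coords <- lapply(labels, function(lab) {
    ref <- switch(lab,
      front = draw_patch(front_centroid),
      back = draw_patch(back_centroid),
      other = draw_other()
    )
    rbind(ref, ref + c(1.5, 0, 0), ref + c(0, 1.5, 0))
  })
  ligand <- Structure(data.frame(
    serial = 1:3, name = c("P1", "O1", "O2"), element = c("P", "O", "O"),
    resname = "FRG", resid = 1L, chain = "L",
    x = pose_coords[[1L]][, 1L], y = pose_coords[[1L]][, 2L],
    z = pose_coords[[1L]][, 3L], stringsAsFactors = FALSE
  ))
  PoseSet(receptor, ligand, pose_coords,
          pose_id = seq_len(n),
          score = -5 - 0.01 * (seq_len(n) - 1L))
}
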