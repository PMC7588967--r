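# Independent oracles and fixture builders. The oracles deliberately use
# naive nested loops, separate from the vectorized implementation paths
# they check.

# Brute-force stability-score oracle: enumerate all heavy receptor x ligand
# pairs within the cutoff at frame 1, then recount per frame.
oracle_ss <- function(frames, rec_idx, lig_idx, elements, cutoff = 7) {
  heavy <- !(toupper(elements) %in% c("H", "D"))
  rec_idx <- rec_idx[heavy[rec_idx]]
  lig_idx <- lig_idx[heavy[lig_idx]]
  f0 <- frames[[1L]]
  native <- list()
  for (i in rec_idx) {
    for (j in lig_idx) {
      if (sqrt(sum((f0[i, ] - f0[j, ])^2)) <= cutoff) {
        native[[length(native) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(native) == 0L) stop("oracle: no native pairs")
  sapply(frames, function(f) {
    kept <- 0L
    for (p in native) {
      if (sqrt(sum((f[p[1L], ] - f[p[2L], ])^2)) <= cutoff) kept <- kept + 1L
    }
    kept / length(native)
  })
}

# Brute-force truncated LJ + Coulomb oracle over explicit pair loops.
oracle_lj_coulomb <- function(frame, rec_idx, lig_idx, charge, epsilon,
                              rmin_half, cutoff = 10) {
  vdw <- 0
  ele <- 0
  for (i in rec_idx) {
    for (j in lig_idx) {
      r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
      if (r > cutoff) next
      eij <- sqrt(epsilon[i] * epsilon[j])
      rij <- rmin_half[i] + rmin_half[j]
      vdw <- vdw + eij * ((rij / r)^12 - 2 * (rij / r)^6)
      ele <- ele + 332.0637 * charge[i] * charge[j] / r
    }
  }
  c(vdw = vdw, ele = ele)
}

# Random receptor-ligand system for property tests: coordinates in a 12 A
# box, with one ligand atom pinned near a receptor atom so a native pair
# always exists.
random_system <- function(seed, max_atoms = 30L, max_frames = 20L) {
  set.seed(seed)
  n_rec <- sample(2:(max_atoms - 2L), 1L)
  n_lig <- sample(2:min(5L, max_atoms - n_rec), 1L)
  n <- n_rec + n_lig
  nf <- sample(2:max_frames, 1L)
  base <- matrix(runif(3L * n, 0, 12), ncol = 3L)
  base[n_rec + 1L, ] <- base[1L, ] + c(2, 0, 0)
  frames <- lapply(seq_len(nf), function(k) {
    if (k == 1L) base else base + matrix(rnorm(3L * n, sd = 1.5), ncol = 3L)
  })
  list(frames = frames, rec_idx = seq_len(n_rec),
       lig_idx = n_rec + seq_len(n_lig),
       elements = rep("C", n))
}

# Wrap raw frames into a package Trajectory over a generic carbon topology.
frames_to_trajectory <- function(frames, rec_idx, lig_idx,
                                 elements = rep("C", nrow(frames[[1L]]))) {
  n <- nrow(frames[[1L]])
  st <- Structure(data.frame(
    serial = seq_len(n), name = paste0("X", seq_len(n)), element = elements,
    resname = ifelse(seq_len(n) %in% lig_idx, "LIG", "REC"),
    resid = ifelse(seq_len(n) %in% lig_idx, 1L, seq_len(n)),
    chain = ifelse(seq_len(n) %in% lig_idx, "B", "A"),
    x = frames[[1L]][, 1L], y = frames[[1L]][, 2L], z = frames[[1L]][, 3L],
    stringsAsFactors = FALSE
  ))
  Trajectory(st, frames, 1)
}

# The worked 5-atom system: three receptor atoms, two ligand atoms, second
# frame moves the ligand so exactly one of the two native pairs survives.
worked_toy_trajectory <- function() {
  f1 <- rbind(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0), c(0, 3, 0), c(0, 8, 0))
  f2 <- rbind(c(0, 0, 0), c(5, 0, 0), c(20, 0, 0), c(0, 6, 0), c(0, 11, 0))
  frames_to_trajectory(list(f1, f2), rec_idx = 1:3, lig_idx = 4:5)
}

# Minimal hand-written PDB text fixtures (independent of the package's
# writers).
write_fixture_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          element = "") {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, chain, resid, x, y, z, element)
}

# A rigid transform (fixed rotation + translation) applied to a coordinate
# matrix, for invariance tests.
rigid_transform <- function(m) {
  th <- 0.7
  ph <- 1.1
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(ph), -sin(ph)), c(0, sin(ph), cos(ph)))
  m %*% t(Rz %*% Rx) + matrix(c(11, -7, 3), nrow(m), 3L, byrow = TRUE)
}
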