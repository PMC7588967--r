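# Framewise native-contact stability score (SS).
#
# Native pairs are the receptor-ligand heavy-atom pairs within the cutoff
# (default 7 A, closed boundary) in the reference frame; the SS of any frame
# is the fraction of those pairs still within the cutoff. SS of the
# reference frame is therefore always 1, and every SS lies in [0, 1].

#' Select heavy atoms matching a residue/chain predicate
#'
#' Returns topology-order indices of atoms that match the given chain,
#' residue-number and/or residue-name filters and are heavy (element is
#' neither H nor D — deuterium is an isotope of hydrogen and is excluded
#' too).
#'
#' @param structure a [Structure].
#' @param chain optional chain id(s) to keep.
#' @param resid optional residue number(s) to keep.
#' @param resname optional residue name(s) to keep.
#' @return integer vector of atom indices (1-based, topology order).
#' @export
select_heavy_atoms <- function(structure, chain = NULL, resid = NULL,
                               resname = NULL) {
  stopifnot(inherits(structure, "Structure"))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!any(keep)) stop("selection matches no atoms")
  idx <- which(keep & !(toupper(at$element) %in% c("H", "D")))
  idx
}

# All cross distances between coordinate blocks A (m x 3) and B (n x 3).
.cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * (A %*% t(B))
  sqrt(pmax(d2, 0))
}

#' Native receptor-ligand heavy-atom pairs
#'
#' Enumerates all receptor x ligand atom pairs whose Euclidean distance in
#' the reference frame is within `cutoff_A` (closed boundary: a pair at
#' exactly the cutoff is native). Only cross pairs are considered — the
#' score measures the stability of the receptor-ligand interaction, and
#' intra-molecular pairs would dilute it. Indices containing hydrogens are
#' dropped with a warning.
#'
#' @param traj a [Trajectory].
#' @param receptor_atoms heavy-atom indices of the receptor.
#' @param ligand_atoms heavy-atom indices of the ligand (disjoint from
#'   `receptor_atoms`).
#' @param cutoff_A distance cutoff in Angstrom (default 7).
#' @param reference_frame 0-based frame defining the native set (default 0,
#'   the initial frame).
#' @return an object of class `"NativePairSet"`: a list with a two-column
#'   `pairs` matrix (receptor index, ligand index), the cutoff, the
#'   reference frame, and the atom selections.
#' @export
native_pairs <- function(traj, receptor_atoms, ligand_atoms, cutoff_A = 7.0,
                         reference_frame = 0L) {
  stopifnot(inherits(traj, "Trajectory"), n_frames(traj) >= 1L)
  if (length(intersect(receptor_atoms, ligand_atoms)) > 0L) {
    stop("receptor and ligand atom selections must be disjoint")
  }
  elem <- toupper(traj$topology$atoms$element)
  drop_r <- elem[receptor_atoms] %in% c("H", "D")
  drop_l <- elem[ligand_atoms] %in% c("H", "D")
  if (any(drop_r) || any(drop_l)) {
    warning("dropping ", sum(drop_r) + sum(drop_l),
            " hydrogen/deuterium atom(s) from the native-pair selections")
    receptor_atoms <- receptor_atoms[!drop_r]
    ligand_atoms <- ligand_atoms[!drop_l]
  }
  if (length(receptor_atoms) == 0L || length(ligand_atoms) == 0L) {
    stop("empty heavy-atom selection")
  }
  ref <- traj$frames[[reference_frame + 1L]]
  D <- .cross_dist(ref[receptor_atoms, , drop = FALSE],
                   ref[ligand_atoms, , drop = FALSE])
  hit <- which(D <= cutoff_A, arr.ind = TRUE)
  pairs <- cbind(receptor = receptor_atoms[hit[, 1L]],
                 ligand = ligand_atoms[hit[, 2L]])
  if (nrow(pairs) == 0L) {
    warning("no native contacts within ", cutoff_A,
            " A in the reference frame; stability score will be undefined")
  }
  structure(list(pairs = pairs, cutoff_A = cutoff_A,
                 reference_frame = as.integer(reference_frame),
                 receptor_atoms = receptor_atoms,
                 ligand_atoms = ligand_atoms),
            class = "NativePairSet")
}

#' @export
print.NativePairSet <- function(x, ...) {
  cat("NativePairSet:", nrow(x$pairs), "pairs within", x$cutoff_A,
      "A at frame", x$reference_frame, "\n")
  invisible(x)
}

.new_stability_series <- function(frame, time_ns, ss, frame_interval_ns,
                                  n_native_pairs) {
  df <- data.frame(frame = frame, time_ns = time_ns, ss = ss)
  attr(df, "frame_interval_ns") <- frame_interval_ns
  attr(df, "n_native_pairs") <- n_native_pairs
  class(df) <- c("StabilitySeries", "data.frame")
  df
}

#' Framewise stability score
#'
#' For every frame, the fraction of native pairs whose distance is still
#' within the cutoff. The value at the reference frame is 1 by construction
#' and every value lies in `[0, 1]`. No periodic-boundary imaging is
#' applied — inputs are assumed imaged, whole molecules. As a guard,
#' ligand atom pairs bonded in the reference frame (within 2 A) that
#' stretch by more than 3 A beyond their reference length in any frame
#' trigger a one-time warning: a jump of that size is a wrapping artifact,
#' not thermal motion.
#'
#' @param traj a [Trajectory].
#' @param pairs a [native_pairs()] result (non-empty).
#' @return a `StabilitySeries`: data.frame with columns `frame` (0-based),
#'   `time_ns` and `ss`, carrying attributes `frame_interval_ns` and
#'   `n_native_pairs`.
#' @export
stability_series <- function(traj, pairs) {
  stopifnot(inherits(traj, "Trajectory"), inherits(pairs, "NativePairSet"))
  if (nrow(pairs$pairs) == 0L) {
    stop("no native contacts; stability score undefined")
  }
  ri <- pairs$pairs[, 1L]
  li <- pairs$pairs[, 2L]
  cutoff <- pairs$cutoff_A
  lig <- pairs$ligand_atoms
  # intra-ligand pairs bonded in the reference frame, for the wrap guard
  ref <- traj$frames[[pairs$reference_frame + 1L]]
  bonds <- NULL
  if (length(lig) >= 2L) {
    DL <- .cross_dist(ref[lig, , drop = FALSE], ref[lig, , drop = FALSE])
    hit <- which(upper.tri(DL) & DL <= 2, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      bonds <- list(a = lig[hit[, 1L]], b = lig[hit[, 2L]],
                    ref_len = DL[hit])
    }
  }
  warned_wrap <- FALSE
  ss <- vapply(traj$frames, function(f) {
    d <- sqrt(rowSums((f[ri, , drop = FALSE] - f[li, , drop = FALSE])^2))
    if (!warned_wrap && !is.null(bonds)) {
      bl <- sqrt(rowSums((f[bonds$a, , drop = FALSE] -
                            f[bonds$b, , drop = FALSE])^2))
      if (any(bl - bonds$ref_len > 3)) {
        warning("intra-ligand bonded distance jumped by > 3 A; ",
                "possible periodic-wrapping artifact", call. = FALSE)
        warned_wrap <<- TRUE
      }
    }
    mean(d <= cutoff)
  }, numeric(1))
  n <- length(ss)
  .new_stability_series(
    frame = seq_len(n) - 1L,
    time_ns = (seq_len(n) - 1L) * traj$frame_interval_ns,
    ss = ss,
    frame_interval_ns = traj$frame_interval_ns,
    n_native_pairs = nrow(pairs$pairs)
  )
}

#' @export
print.StabilitySeries <- function(x, ...) {
  cat("StabilitySeries:", nrow(x), "frames,",
      attr(x, "n_native_pairs"), "native pairs; mean SS",
      format(mean(x$ss), digits = 4), "\n")
  invisible(x)
}

#' Extract the equilibrated production window
#'
#' Returns the suffix of the series beginning at
#' `floor(start_fraction * n_frames)` (0-based). The default of 0.5
#' reproduces the last 100 ns of a 200-frame / 200-ns trajectory — the
#' window over which all downstream statistics are computed.
#'
#' @param series a `StabilitySeries` (or any data.frame with a `frame`
#'   column) of at least 2 frames.
#' @param start_fraction fraction of the trajectory to discard as
#'   equilibration, in `[0, 1)`.
#' @return the windowed series, same class and attributes.
#' @export
production_window <- function(series, start_fraction = 0.5) {
  stopifnot(start_fraction >= 0, start_fraction < 1)
  n <- nrow(series)
  if (n < 2L) stop("series must have at least 2 frames")
  start <- floor(start_fraction * n) + 1L
  out <- series[start:n, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "frame_interval_ns") <- attr(series, "frame_interval_ns")
  attr(out, "n_native_pairs") <- attr(series, "n_native_pairs")
  class(out) <- class(series)
  out
}

#' Mean stability score of a series
#' @param series a `StabilitySeries` (non-empty).
#' @return arithmetic mean of the SS values.
#' @export
mean_ss <- function(series) {
  stopifnot(nrow(series) >= 1L)
  mean(series$ss)
}

#' Detect a sustained ligand exit
#'
#' A ligand has exited its original binding site when the stability score
#' stays below `exit_threshold` for `sustain_frames` consecutive frames;
#' short dips that recover are not exits. The thresholds operationalize
#' the qualitative observation of a ligand leaving the binding pocket.
#'
#' @param series a `StabilitySeries`.
#' @param exit_threshold SS below which the ligand counts as unbound
#'   (default 0.1).
#' @param sustain_frames minimum run length of sub-threshold frames
#'   (default 10; must be >= 1).
#' @return the 0-based frame index at which the sustained exit begins, or
#'   `NA_integer_` if the ligand never exits.
#' @export
detect_exit <- function(series, exit_threshold = 0.1, sustain_frames = 10L) {
  stopifnot(nrow(series) >= 1L)
  if (sustain_frames < 1L) stop("sustain_frames must be >= 1")
  below <- series$ss < exit_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= sustain_frames)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(series$frame[starts[hit[1L]]])
}
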