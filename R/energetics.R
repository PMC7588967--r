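# MM-PBSA decomposition and the LJ/Coulomb cross-interaction stand-in.
#
# dGvdw = VDWAALS + ENPOLAR captures packing/hydrophobic effects,
# dGele = EEL + EPB the electrostatic ones, dGtotal their sum. The PB and
# nonpolar-solvation terms are parsed from tables, never computed here; the
# pairwise calculator covers only the molecular-mechanics cross terms so the
# pipeline can be exercised end-to-end on synthetic structures.

#' Decompose an energy series into binding free-energy components
#'
#' For an [EnergySeries] this computes the per-frame component sums; for
#' any other object it forwards to [stats::decompose()] (classical
#' time-series decomposition), which this generic otherwise masks.
#'
#' @param series an [EnergySeries] (or a time series, forwarded to
#'   \pkg{stats}).
#' @param ... passed to [stats::decompose()] by the default method.
#' @return data.frame of class `"DecomposedEnergySeries"` with the four
#'   parsed terms plus `dG_vdw`, `dG_ele`, `dG_total` per frame (kcal/mol)
#'   and a `provenance` attribute (`"parsed"`).
#' @export
decompose <- function(series, ...) UseMethod("decompose")

#' @rdname decompose
#' @export
decompose.default <- function(series, ...) stats::decompose(series, ...)

#' @rdname decompose
#' @export
decompose.EnergySeries <- function(series, ...) {
  out <- as.data.frame(series)
  out$dG_vdw <- out$VDWAALS + out$ENPOLAR
  out$dG_ele <- out$EEL + out$EPB
  out$dG_total <- out$dG_vdw + out$dG_ele
  attr(out, "provenance") <- "parsed"
  class(out) <- c("DecomposedEnergySeries", "data.frame")
  out
}

#' @export
summary.DecomposedEnergySeries <- function(object, ...) {
  comp <- c("dG_vdw", "dG_ele", "dG_total")
  data.frame(
    component = comp,
    mean = vapply(comp, function(cn) mean(object[[cn]]), numeric(1)),
    sd = vapply(comp, function(cn) stats::sd(object[[cn]]), numeric(1)),
    row.names = NULL
  )
}

#' Framewise Pearson correlation between two energy (or SS) series
#'
#' Standard product-moment correlation with a two-sided t-test on n - 2
#' degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return list with `r` (in `[-1, 1]`), `p_value`, `n`.
#' @export
framewise_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 paired frames")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate series: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Select the representative replicate
#'
#' Among replicate trajectories of one complex, downstream energetic
#' analysis uses the trajectory with the highest average stability score
#' over the production window. Exact ties are broken toward the lowest
#' index, with a message.
#'
#' @param replicates list of `StabilitySeries`, all of the same length.
#' @param start_fraction production-window start, see [production_window()].
#' @return 1-based index of the selected replicate.
#' @export
select_representative_replicate <- function(replicates, start_fraction = 0.5) {
  stopifnot(length(replicates) >= 1L)
  lens <- vapply(replicates, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("replicate series differ in length")
  means <- vapply(replicates, function(s) {
    mean_ss(production_window(s, start_fraction))
  }, numeric(1))
  best <- which(means == max(means))
  if (length(best) > 1L) {
    message("tie on mean SS between replicates ",
            paste(best, collapse = ", "), "; selecting replicate ", best[1L])
  }
  best[1L]
}

#' Nonbonded force-field parameters for the pairwise calculator
#'
#' @param charge partial charges (elementary charge units).
#' @param epsilon Lennard-Jones well depths (kcal/mol, >= 0).
#' @param rmin_half Lennard-Jones rmin/2 radii (Angstrom).
#' @return data.frame of class `"NonbondedParams"`, one row per atom.
#' @export
nonbonded_params <- function(charge, epsilon, rmin_half) {
  stopifnot(length(charge) == length(epsilon),
            length(charge) == length(rmin_half),
            all(is.finite(charge)), all(is.finite(epsilon)),
            all(is.finite(rmin_half)), all(epsilon >= 0))
  out <- data.frame(charge = charge, epsilon = epsilon, rmin_half = rmin_half)
  class(out) <- c("NonbondedParams", "data.frame")
  out
}

#' Coulomb constant, kcal * Angstrom / (mol * e^2), Amber convention.
#' @export
COULOMB_K <- 332.0637

#' Truncated Lennard-Jones + Coulomb cross-interaction energy
#'
#' Sums, over all receptor x ligand pairs within `cutoff_A` (hard
#' truncation, no switching function):
#' \deqn{E_{vdw} = \sum \epsilon_{ij}\left[(r_{min,ij}/r)^{12} -
#'   2 (r_{min,ij}/r)^{6}\right], \quad
#'   E_{ele} = \sum k\, q_i q_j / r}
#' with Lorentz-Berthelot combining (\eqn{\epsilon_{ij} =
#' \sqrt{\epsilon_i \epsilon_j}}, \eqn{r_{min,ij} = r_{min,i}/2 +
#' r_{min,j}/2}) and k = 332.0637 kcal A / (mol e^2), vacuum dielectric.
#' This is a molecular-mechanics cross-term calculator for exercising the
#' decomposition pipeline, not a solvation model.
#'
#' @param frame n_atoms x 3 coordinate matrix (Angstrom).
#' @param receptor_atoms,ligand_atoms disjoint atom index vectors.
#' @param params a [nonbonded_params()] table covering all topology atoms
#'   (row i = atom i).
#' @param cutoff_A nonbonded cutoff in Angstrom (default 10).
#' @return named numeric vector `c(vdw = ..., ele = ...)` in kcal/mol.
#' @export
lj_coulomb_interaction <- function(frame, receptor_atoms, ligand_atoms,
                                   params, cutoff_A = 10.0) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L,
            inherits(params, "NonbondedParams"))
  if (length(intersect(receptor_atoms, ligand_atoms)) > 0L) {
    stop("receptor and ligand selections must be disjoint")
  }
  if (max(c(receptor_atoms, ligand_atoms)) > nrow(params)) {
    stop("params table does not cover all selected atoms")
  }
  R <- frame[receptor_atoms, , drop = FALSE]
  L <- frame[ligand_atoms, , drop = FALSE]
  D <- .cross_dist(R, L)
  within <- D <= cutoff_A
  if (!any(within)) return(c(vdw = 0, ele = 0))
  if (any(D[within] < 0.1)) {
    stop("atomic clash: pair distance below 0.1 A")
  }
  eps <- sqrt(outer(params$epsilon[receptor_atoms],
                    params$epsilon[ligand_atoms]))
  rmin <- outer(params$rmin_half[receptor_atoms],
                params$rmin_half[ligand_atoms], "+")
  qq <- outer(params$charge[receptor_atoms], params$charge[ligand_atoms])
  x6 <- (rmin[within] / D[within])^6
  vdw <- sum(eps[within] * (x6^2 - 2 * x6))
  ele <- COULOMB_K * sum(qq[within] / D[within])
  c(vdw = vdw, ele = ele)
}
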