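# Front-patch / back-patch assignment of docking poses.
#
# The two patches are the opposite entrances of the KR substrate channel:
# front R38/R65/R93 (the arginine cluster that grips the phosphopantetheine
# phosphate) and back Q149/R220/N260. Poses are assigned by the distance of
# a pose reference point to each patch centroid, replacing visual
# assessment in a molecular viewer with a reproducible rule.

#' Define a binding patch
#'
#' @param name patch label, e.g. `"front"`.
#' @param residues data.frame with columns `chain` and `resid`, or a
#'   character vector like `c("A:38", "A:65", "A:93")`.
#' @param centroid_rule `"all-heavy"` (default) or `"side-chain-heavy"`
#'   (excludes backbone N, CA, C, O, OXT).
#' @return an object of class `"PatchDefinition"`.
#' @export
patch_definition <- function(name, residues,
                             centroid_rule = c("all-heavy", "side-chain-heavy")) {
  centroid_rule <- match.arg(centroid_rule)
  if (is.character(residues)) {
    parts <- strsplit(residues, ":", fixed = TRUE)
    residues <- data.frame(
      chain = vapply(parts, `[`, character(1), 1L),
      resid = as.integer(vapply(parts, `[`, character(1), 2L)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(is.data.frame(residues), nrow(residues) >= 1L,
            all(c("chain", "resid") %in% names(residues)))
  structure(list(name = name, residues = residues,
                 centroid_rule = centroid_rule),
            class = "PatchDefinition")
}

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Centroid of a binding patch
#'
#' Unweighted mean of the selected heavy-atom coordinates over all patch
#' residues.
#'
#' @param receptor a [Structure].
#' @param patch a [patch_definition()].
#' @return numeric length-3 vector (Angstrom).
#' @export
patch_centroid <- function(receptor, patch) {
  stopifnot(inherits(receptor, "Structure"), inherits(patch, "PatchDefinition"))
  at <- receptor$atoms
  idx <- integer(0)
  for (i in seq_len(nrow(patch$residues))) {
    ch <- patch$residues$chain[i]
    rs <- patch$residues$resid[i]
    sel <- which(at$chain == ch & at$resid == rs &
                   !(toupper(at$element) %in% c("H", "D")))
    if (patch$centroid_rule == "side-chain-heavy") {
      sel <- sel[!(at$name[sel] %in% .backbone_names)]
    }
    if (length(sel) == 0L) stop("residue ", ch, ":", rs, " not found")
    idx <- c(idx, sel)
  }
  colMeans(coords(receptor)[idx, , drop = FALSE])
}

#' Reference point of a ligand pose
#'
#' The phosphate anchors the observed front-patch interaction, so the
#' default reference point is the (first) phosphorus atom; ligands without
#' phosphorus fall back to the heavy-atom centroid with a warning.
#'
#' @param pose_coords n_atoms x 3 coordinate matrix of one pose.
#' @param elements element symbols for the pose atoms.
#' @param rule `"phosphorus"` (default) or `"centroid"`.
#' @return numeric length-3 vector (Angstrom).
#' @export
pose_reference_point <- function(pose_coords, elements,
                                 rule = c("phosphorus", "centroid")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(pose_coords), ncol(pose_coords) == 3L,
            length(elements) == nrow(pose_coords))
  elements <- toupper(elements)
  if (rule == "phosphorus") {
    p <- which(elements == "P")
    if (length(p) >= 1L) return(as.numeric(pose_coords[p[1L], ]))
    warning("no phosphorus atom in pose; falling back to heavy-atom centroid")
  }
  heavy <- !(elements %in% c("H", "D"))
  colMeans(pose_coords[heavy, , drop = FALSE])
}

#' Classify one pose against the front and back patches
#'
#' The pose is labelled with the nearer patch (reference point to patch
#' centroid) provided that distance is within `threshold_A`; otherwise
#' `"other"`. Ties closer than 1e-6 A are unresolvable and also go to
#' `"other"`.
#'
#' @param pose_coords n_atoms x 3 coordinate matrix of one pose.
#' @param elements element symbols for the pose atoms.
#' @param receptor a [Structure].
#' @param front,back [patch_definition()]s.
#' @param threshold_A patch acceptance radius in Angstrom (default 8).
#' @param rule reference-point rule, see [pose_reference_point()].
#' @return one-row data.frame: `label` (front/back/other),
#'   `distance_to_front_A`, `distance_to_back_A`.
#' @export
classify_pose <- function(pose_coords, elements, receptor, front, back,
                          threshold_A = 8.0,
                          rule = c("phosphorus", "centroid")) {
  ref <- pose_reference_point(pose_coords, elements, rule)
  cf <- patch_centroid(receptor, front)
  cb <- patch_centroid(receptor, back)
  df <- sqrt(sum((ref - cf)^2))
  db <- sqrt(sum((ref - cb)^2))
  label <- if (min(df, db) > threshold_A || abs(df - db) < 1e-6) {
    "other"
  } else if (df < db) "front" else "back"
  data.frame(label = label, distance_to_front_A = df, distance_to_back_A = db,
             stringsAsFactors = FALSE)
}

#' Classify every pose of a PoseSet
#'
#' @param ps a [PoseSet].
#' @inheritParams classify_pose
#' @return data.frame of class `"PoseAssignments"`: one row per pose with
#'   `pose_id`, `label`, `distance_to_front_A`, `distance_to_back_A`.
#' @export
classify_poses <- function(ps, front, back, threshold_A = 8.0,
                           rule = c("phosphorus", "centroid")) {
  stopifnot(inherits(ps, "PoseSet"))
  rule <- match.arg(rule)
  elements <- ps$ligand$atoms$element
  cf <- patch_centroid(ps$receptor, front)
  cb <- patch_centroid(ps$receptor, back)
  rows <- lapply(seq_along(ps$pose_coords), function(i) {
    ref <- suppressWarnings(
      pose_reference_point(ps$pose_coords[[i]], elements, rule)
    )
    df <- sqrt(sum((ref - cf)^2))
    db <- sqrt(sum((ref - cb)^2))
    label <- if (min(df, db) > threshold_A || abs(df - db) < 1e-6) {
      "other"
    } else if (df < db) "front" else "back"
    data.frame(pose_id = ps$pose_id[i], label = label,
               distance_to_front_A = df, distance_to_back_A = db,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("PoseAssignments", "data.frame")
  out
}

#' Tabulate pose assignments into a motif frequency table
#'
#' Counts and percentages per label, percentages reported to one decimal
#' place (the field's conventional reporting precision).
#'
#' @param assignments data.frame with a `label` column (>= 1 row).
#' @return data.frame of class `"MotifTable"` with columns `label`,
#'   `count`, `percent`, plus attribute `n_poses`.
#' @export
tabulate_assignments <- function(assignments) {
  if (nrow(assignments) == 0L) stop("no assignments to tabulate")
  labels <- c("front", "back", "other")
  counts <- vapply(labels, function(l) sum(assignments$label == l), integer(1))
  n <- nrow(assignments)
  out <- data.frame(label = labels, count = as.integer(counts),
                    percent = round(100 * counts / n, 1L),
                    stringsAsFactors = FALSE)
  attr(out, "n_poses") <- n
  class(out) <- c("MotifTable", "data.frame")
  out
}
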