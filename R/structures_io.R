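# Two-letter element symbols that can plausibly open a PDB atom name in
# protein/ligand/ion contexts. Checked only for non-standard residues, so
# "CA" in an amino acid is always the alpha carbon, never calcium.
.two_letter_elements <- c(
  "FE", "ZN", "MG", "MN", "CU", "NI", "CO", "SE", "MO", "CD", "HG",
  "CL", "BR", "NA", "SI", "AL", "LI", "BE", "RB", "SR", "CS", "BA", "AS"
)

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HID", "HIE", "HIP", "CYX", "HOH", "WAT",
  "A", "C", "G", "U", "DA", "DC", "DG", "DT"
)

#' Infer an element symbol from a PDB atom name
#'
#' Applies the PDB v3.3 naming convention for records whose element column
#' (cols 77-78) is blank: digits and primes are stripped from the atom name;
#' for standard residues the element is the first remaining letter (so
#' `"CA"` in `ALA` is carbon, `"1HB"` is hydrogen), while for hetero
#' residues a leading two-letter match against known metal/halogen symbols
#' (`FE`, `CL`, `ZN`, ...) takes precedence, and a monoatomic ion whose
#' residue name equals its atom name is taken verbatim.
#'
#' @param name character vector of PDB atom names.
#' @param resname character vector of residue names (same length).
#' @return character vector of element symbols.
#' @export
#' @examples
#' infer_element(c("CA", "1HB", "FE"), c("ALA", "ALA", "HEM"))
infer_element <- function(name, resname) {
  stopifnot(length(name) == length(resname))
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  resname <- toupper(trimws(resname))
  out <- character(length(name))
  for (i in seq_along(name)) {
    nm <- stripped[i]
    if (nchar(nm) == 0L) {
      stop("cannot infer element for atom with name '", name[i], "'")
    }
    two <- substr(nm, 1L, 2L)
    if (resname[i] %in% .standard_residues) {
      out[i] <- substr(nm, 1L, 1L)
    } else if (nm == resname[i] && two %in% .two_letter_elements) {
      out[i] <- two
    } else if (nchar(nm) >= 2L && two %in% .two_letter_elements) {
      out[i] <- two
    } else {
      out[i] <- substr(nm, 1L, 1L)
    }
  }
  out
}

#' Construct a Structure
#'
#' A `Structure` is the package's container for one model of a molecular
#' system: an atom table (PDB-style fields, coordinates in Angstrom) plus
#' free-form metadata. Residue numbering is kept exactly as in the source
#' file (patch definitions cite crystal-structure numbering).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`.
#' @param metadata named list of free-form metadata.
#' @return an object of class `"Structure"`.
#' @export
Structure <- function(atoms, metadata = list()) {
  required <- c("serial", "name", "element", "resname", "resid",
                "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) {
    stop("atom serial numbers must be unique within a structure")
  }
  if (any(!nzchar(atoms$element)) || anyNA(atoms$element)) {
    stop("every atom must carry a non-empty element symbol")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  atoms <- as.data.frame(atoms[, required], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, metadata = metadata), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), "residues,",
      "chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a Structure
#' @param x a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Coordinates of a Structure as a matrix
#' @param x a `Structure`.
#' @return numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @export
coords <- function(x) {
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

# Convert one row-block of a bio3d pdb object + xyz row into a Structure.
.bio3d_to_structure <- function(pdb, xyz_row, path) {
  at <- pdb$atom
  elem <- at$elesy
  blank <- is.na(elem) | !nzchar(trimws(elem))
  if (any(blank)) {
    elem[blank] <- infer_element(at$elety[blank], at$resid[blank])
  }
  elem <- trimws(elem)
  xyz <- matrix(xyz_row, ncol = 3L, byrow = TRUE)
  chain <- at$chain
  chain[is.na(chain)] <- ""
  Structure(
    data.frame(
      serial = at$eleno, name = at$elety, element = elem,
      resname = at$resid, resid = at$resno, chain = chain,
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE
    ),
    metadata = list(source = path)
  )
}

.read_pdb_checked <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  # pre-scan coordinate fields so parse errors can name the offending line
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    fields <- c(substr(lines[i], 31L, 38L), substr(lines[i], 39L, 46L),
                substr(lines[i], 47L, 54L))
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("malformed coordinate field at line ", i, " of ", path)
    }
  }
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE))
}

#' Read one model of a PDB file
#'
#' Parses all ATOM/HETATM records of the requested MODEL block (via
#' \pkg{bio3d}). Coordinates are in Angstrom; residue numbering is preserved
#' as printed; hydrogens are retained (heavy-atom filtering happens
#' downstream in [select_heavy_atoms()]). A blank element column is filled
#' by [infer_element()].
#'
#' @param path PDB file path.
#' @param model_index 1-based model number (default 1, the first model).
#' @return a [Structure].
#' @export
read_structure <- function(path, model_index = 1L) {
  pdb <- .read_pdb_checked(path, multi = TRUE)
  n_models <- nrow(pdb$xyz)
  if (is.null(n_models)) n_models <- 1L
  if (model_index < 1L || model_index > n_models) {
    stop("model ", model_index, " not present in ", path,
         " (file has ", n_models, " model(s))")
  }
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model_index, ] else as.numeric(pdb$xyz)
  .bio3d_to_structure(pdb, xyz, path)
}

#' Construct a Trajectory
#'
#' Ordered coordinate frames over a fixed topology. One frame corresponds to
#' one structural snapshot; the default spacing of 1 ns matches snapshots
#' extracted every nanosecond from a production MD run.
#'
#' @param topology a [Structure] giving atom identities.
#' @param frames list of numeric matrices (n_atoms x 3, Angstrom).
#' @param frame_interval_ns time between consecutive frames (ns, > 0).
#' @return an object of class `"Trajectory"`.
#' @export
Trajectory <- function(topology, frames, frame_interval_ns = 1) {
  stopifnot(inherits(topology, "Structure"), length(frames) >= 1L,
            is.numeric(frame_interval_ns), frame_interval_ns > 0)
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != na) {
      stop("frame ", i, " has ", if (is.matrix(f)) nrow(f) else length(f),
           " atoms; topology has ", na)
    }
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval_ns = frame_interval_ns),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames x", n_atoms(x$topology),
      "atoms;", x$frame_interval_ns, "ns/frame\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a multi-model PDB trajectory
#'
#' The canonical on-disk trajectory dialect is multi-model PDB (one MODEL
#' block per snapshot), self-contained and plain text. Every frame must have
#' exactly as many atoms as the topology.
#'
#' @param topology_path PDB file defining the topology (first model used).
#' @param frames_path multi-model PDB of coordinate frames.
#' @param frame_interval_ns snapshot spacing in ns (default 1).
#' @return a [Trajectory].
#' @export
read_trajectory <- function(topology_path, frames_path, frame_interval_ns = 1) {
  topology <- read_structure(topology_path)
  pdb <- .read_pdb_checked(frames_path, multi = TRUE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  na <- n_atoms(topology)
  frames <- vector("list", nrow(xyz))
  for (i in seq_len(nrow(xyz))) {
    row <- xyz[i, ]
    if (length(row) != 3L * na) {
      stop("atom-count mismatch at frame ", i, ": topology has ", na,
           " atoms, frame has ", length(row) / 3)
    }
    frames[[i]] <- matrix(row, ncol = 3L, byrow = TRUE,
                          dimnames = list(NULL, c("x", "y", "z")))
  }
  Trajectory(topology, frames, frame_interval_ns)
}

#' Construct a PoseSet
#'
#' A collection of docked ligand poses over a common ligand topology,
#' against one receptor structure. If scores are present the poses must be
#' ordered by non-increasing score (docking programs emit best-first).
#'
#' @param receptor a [Structure].
#' @param ligand a [Structure] for the ligand topology (model 1 atoms).
#' @param pose_coords list of n_ligand_atoms x 3 matrices.
#' @param pose_id vector of unique pose identifiers.
#' @param score optional numeric vector of docking scores (non-increasing).
#' @return an object of class `"PoseSet"`.
#' @export
PoseSet <- function(receptor, ligand, pose_coords, pose_id = seq_along(pose_coords),
                    score = NULL) {
  stopifnot(inherits(receptor, "Structure"), inherits(ligand, "Structure"))
  if (length(pose_coords) == 0L) stop("pose set is empty (zero models)")
  for (pc in pose_coords) {
    if (!is.matrix(pc) || ncol(pc) != 3L || nrow(pc) != n_atoms(ligand)) {
      stop("every pose needs one 3-vector per ligand atom")
    }
  }
  if (anyDuplicated(pose_id)) stop("pose_ids must be unique")
  if (!is.null(score)) {
    if (length(score) != length(pose_coords)) {
      stop("score length does not match number of poses")
    }
    if (is.unsorted(rev(score))) {
      stop("pose scores must be non-increasing (best pose first)")
    }
  }
  structure(list(receptor = receptor, ligand = ligand,
                 pose_coords = pose_coords, pose_id = pose_id, score = score),
            class = "PoseSet")
}

#' @export
print.PoseSet <- function(x, ...) {
  cat("PoseSet:", length(x$pose_coords), "poses of",
      n_atoms(x$ligand), "ligand atoms;",
      if (is.null(x$score)) "no scores" else "scored", "\n")
  invisible(x)
}

#' Read a docking pose set
#'
#' Poses are a multi-model PDB of ligand-only coordinates; an optional
#' per-model score is parsed from a `REMARK` line inside each MODEL block
#' (e.g. `REMARK VINA RESULT: -9.1` or `REMARK SCORE -9.1`).
#'
#' @param receptor_path receptor PDB path.
#' @param poses_path multi-model ligand PDB path.
#' @return a [PoseSet] preserving file order.
#' @export
read_pose_set <- function(receptor_path, poses_path) {
  receptor <- read_structure(receptor_path)
  pdb <- .read_pdb_checked(poses_path, multi = TRUE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  ligand <- .bio3d_to_structure(pdb, xyz[1L, ], poses_path)
  pose_coords <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3L, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  # per-model REMARK scores, in MODEL order
  lines <- readLines(poses_path, warn = FALSE)
  rem <- grep("^REMARK", lines, value = TRUE)
  rem <- rem[grepl("(RESULT|SCORE)", rem, ignore.case = TRUE)]
  score <- NULL
  if (length(rem) > 0L) {
    score <- suppressWarnings(as.numeric(
      sub(".*?(-?[0-9]+\\.?[0-9]*)\\s*$", "\\1", rem)
    ))
    if (anyNA(score) || length(score) != length(pose_coords)) {
      stop("could not parse one REMARK score per model in ", poses_path)
    }
  }
  PoseSet(receptor, ligand, pose_coords, pose_id = seq_along(pose_coords),
          score = score)
}

#' Construct an EnergySeries
#'
#' Per-frame MM-PBSA style energy terms in kcal/mol: `VDWAALS` (van der
#' Waals change upon binding), `EEL` (electrostatic), `EPB` (polar
#' solvation) and `ENPOLAR` (nonpolar solvation).
#'
#' @param frames data.frame with columns `frame`, `VDWAALS`, `EEL`, `EPB`,
#'   `ENPOLAR`.
#' @return data.frame of class `"EnergySeries"`.
#' @export
EnergySeries <- function(frames) {
  required <- c("frame", "VDWAALS", "EEL", "EPB", "ENPOLAR")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0L) {
    stop("energy series lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  frames <- as.data.frame(frames[, required], stringsAsFactors = FALSE)
  if (is.unsorted(frames$frame, strictly = TRUE)) {
    stop("frame indices must be strictly increasing")
  }
  for (cn in required[-1L]) {
    if (!all(is.finite(frames[[cn]]))) {
      stop("non-finite value in column ", cn)
    }
  }
  rownames(frames) <- NULL
  class(frames) <- c("EnergySeries", "data.frame")
  frames
}

#' Read a per-frame MM-PBSA energy table
#'
#' Accepts comma-, tab- or whitespace-delimited text with a header row
#' containing at least VDWAALS, EEL, EPB and ENPOLAR (matched
#' case-insensitively; extra columns such as a precomputed TOTAL are
#' ignored — derived quantities are always recomputed downstream). Frame
#' indices come from an explicit `Frame` column when present, else from row
#' order starting at 0.
#'
#' @param path delimited text file.
#' @return an [EnergySeries].
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  df <- if (grepl(",", first)) {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  upper <- toupper(names(df))
  required <- c("VDWAALS", "EEL", "EPB", "ENPOLAR")
  for (cn in required) {
    if (!cn %in% upper) stop("missing required column: ", cn)
  }
  get_col <- function(cn) {
    v <- df[[which(upper == cn)[1L]]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0L) {
      stop("non-numeric cell at row ", bad[1L], ", column ", cn)
    }
    num
  }
  frame <- if ("FRAME" %in% upper) get_col("FRAME") else seq_len(nrow(df)) - 1L
  EnergySeries(data.frame(
    frame = frame,
    VDWAALS = get_col("VDWAALS"), EEL = get_col("EEL"),
    EPB = get_col("EPB"), ENPOLAR = get_col("ENPOLAR")
  ))
}

#' Write a result table as CSV
#'
#' UTF-8, '.' decimal separator, header row, deterministic column order
#' (the order of the input data.frame).
#'
#' @param rows data.frame of homogeneous records (may have zero rows).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  utils::write.csv(rows, file = path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a Structure (or coordinate frames over it) as PDB
#'
#' @param x a [Structure].
#' @param path output path.
#' @param frames optional list of n_atoms x 3 matrices; when given, a
#'   multi-model PDB is written (one MODEL per frame).
#' @return invisibly, the path.
#' @export
write_structure <- function(x, path, frames = NULL) {
  stopifnot(inherits(x, "Structure"))
  xyz <- if (is.null(frames)) {
    as.numeric(t(coords(x)))
  } else {
    do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  }
  at <- x$atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$resid, resid = at$resname,
                   eleno = at$serial, elety = at$name,
                   chain = ifelse(nzchar(at$chain), at$chain, " "),
                   elesy = at$element)
  invisible(path)
}

#' Write a Trajectory as multi-model PDB
#' @param traj a [Trajectory].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  write_structure(traj$topology, path, frames = traj$frames)
}

#' Write a PoseSet's ligand poses as multi-model PDB
#'
#' Scores, when present, are emitted as a `REMARK VINA RESULT:` line inside
#' each MODEL block so that [read_pose_set()] round-trips them.
#'
#' @param ps a [PoseSet].
#' @param path output path for the ligand poses.
#' @return invisibly, the path.
#' @export
write_pose_set <- function(ps, path) {
  stopifnot(inherits(ps, "PoseSet"))
  write_structure(ps$ligand, path, frames = ps$pose_coords)
  if (!is.null(ps$score)) {
    lines <- readLines(path, warn = FALSE)
    model_idx <- grep("^MODEL", lines)
    out <- character(0)
    prev <- 1L
    for (k in seq_along(model_idx)) {
      i <- model_idx[k]
      out <- c(out, lines[prev:i],
               sprintf("REMARK VINA RESULT: %10.4f", ps$score[k]))
      prev <- i + 1L
    }
    out <- c(out, lines[prev:length(lines)])
    writeLines(out, path)
  }
  invisible(path)
}
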