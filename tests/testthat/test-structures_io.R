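test_that("read_structure parses records, selects models, and preserves numbering", {
  path <- write_fixture_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 5, 0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 5, 1.5, 0, 0, "C"),
    pdb_atom_line(3, "C", "ALA", "A", 5, 2.5, 1, 0, "C"),
    pdb_atom_line(4, "O", "ALA", "A", 5, 2.5, 2.2, 0, "O"),
    pdb_atom_line(5, "CB", "ALA", "A", 5, 1.5, -1.5, 0, "C"),
    "END"
  ))
  st <- read_structure(path)
  expect_s3_class(st, "Structure")
  expect_equal(n_atoms(st), 5L)
  expect_equal(unique(st$atoms$resid), 5L)  # numbering as printed

  multi <- write_fixture_pdb(c(
    "MODEL        1",
    pdb_atom_line(1, "C1", "LIG", "B", 1, 0, 0, 0, "C"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "C1", "LIG", "B", 1, 9, 9, 9, "C"),
    "ENDMDL",
    "MODEL        3",
    pdb_atom_line(1, "C1", "LIG", "B", 1, 5, 5, 5, "C"),
    "ENDMDL", "END"
  ))
  st2 <- read_structure(multi, model_index = 2L)
  expect_equal(unname(coords(st2)[1, ]), c(9, 9, 9))
  expect_error(read_structure(multi, model_index = 7L), "model")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("a malformed coordinate field is reported with its line number", {
  bad <- pdb_atom_line(1, "C1", "LIG", "B", 1, 0, 0, 0, "C")
  substr(bad, 33, 35) <- "x?z"
  path <- write_fixture_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"), bad, "END"
  ))
  expect_error(read_structure(path), "line 2")
})

test_that("blank element columns are inferred by the PDB naming convention", {
  path <- write_fixture_pdb(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),   # alpha carbon
    pdb_atom_line(2, "1HB", "ALA", "A", 1, 1, 0, 0),  # hydrogen
    pdb_atom_line(3, "FE", "HEM", "A", 2, 2, 0, 0),   # iron
    pdb_atom_line(4, "OD1", "ASP", "A", 3, 3, 0, 0),  # oxygen
    "END"
  ))
  st <- read_structure(path)
  expect_equal(st$atoms$element, c("C", "H", "FE", "O"))
})

test_that("structure round-trip preserves identity and coordinates to PDB precision", {
  cplx <- make_toy_complex(8, 3, seed = 11)
  path <- tempfile(fileext = ".pdb")
  write_structure(cplx$structure, path)
  back <- read_structure(path)
  expect_equal(back$atoms$serial, cplx$structure$atoms$serial)
  expect_equal(back$atoms$name, cplx$structure$atoms$name)
  expect_equal(back$atoms$resid, cplx$structure$atoms$resid)
  expect_equal(coords(back), coords(cplx$structure), tolerance = 1e-3)
})

test_that("read_trajectory enforces frame/topology atom-count agreement", {
  cplx <- make_toy_complex(6, 2, seed = 3)
  spec <- synthetic_spec(seed = 3, n_frames = 20, jitter_sigma_A = 0.2)
  traj <- simulate_bound_trajectory(cplx, spec)
  top <- tempfile(fileext = ".pdb")
  frames <- tempfile(fileext = ".pdb")
  write_structure(cplx$structure, top)
  write_trajectory(traj, frames)
  back <- read_trajectory(top, frames)
  expect_equal(n_frames(back), 20L)
  expect_equal(back$frames[[7]], traj$frames[[7]], tolerance = 1e-3,
               ignore_attr = TRUE)

  one <- tempfile(fileext = ".pdb")
  write_structure(cplx$structure, one)
  expect_equal(n_frames(read_trajectory(top, one)), 1L)

  # frames file over a smaller topology than declared
  small <- make_toy_complex(5, 2, seed = 3)
  mismatch <- tempfile(fileext = ".pdb")
  write_structure(small$structure, mismatch)
  expect_error(read_trajectory(top, mismatch), "frame 1")
})

test_that("pose sets round-trip with per-model REMARK scores", {
  rec <- make_toy_complex(8, 1, seed = 5)$structure
  spec <- synthetic_spec(seed = 5, n_poses = 12)
  ps <- simulate_pose_set(rec, c(0, 0, 0), c(24, 0, 0), spec)
  rp <- tempfile(fileext = ".pdb")
  pp <- tempfile(fileext = ".pdb")
  write_structure(rec, rp)
  write_pose_set(ps, pp)
  back <- read_pose_set(rp, pp)
  expect_length(back$pose_coords, 12L)
  expect_equal(back$score, ps$score, tolerance = 1e-4)
  expect_equal(back$pose_coords[[4]], ps$pose_coords[[4]], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("unsorted pose scores and scoreless pose files are handled per contract", {
  rec <- make_toy_complex(4, 1, seed = 2)$structure
  lig <- Structure(data.frame(
    serial = 1L, name = "C1", element = "C", resname = "LIG", resid = 1L,
    chain = "B", x = 0, y = 0, z = 0, stringsAsFactors = FALSE
  ))
  cs <- list(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  expect_error(PoseSet(rec, lig, cs, score = c(-9, -5)), "non-increasing")
  expect_silent(ps <- PoseSet(rec, lig, cs))
  expect_null(ps$score)
  # no REMARK lines on disk -> scores absent after reading
  rp <- tempfile(fileext = ".pdb")
  pp <- tempfile(fileext = ".pdb")
  write_structure(rec, rp)
  write_pose_set(ps, pp)
  expect_null(read_pose_set(rp, pp)$score)
})

test_that("energy tables parse case-insensitively, ignore extras, and name bad cells", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("frame,vdwaals,EEL,Epb,ENPOLAR,TOTAL",
               "0,-40,-30,60,-5,-15",
               "1,-41,-29,59,-6,-17"), path)
  es <- read_energy_table(path)
  expect_s3_class(es, "EnergySeries")
  expect_equal(nrow(es), 2L)
  expect_equal(es$VDWAALS, c(-40, -41))
  expect_false("TOTAL" %in% names(es))  # derived columns are never trusted

  # whitespace-delimited dialect, no Frame column -> row order from 0
  path2 <- tempfile(fileext = ".dat")
  writeLines(c("VDWAALS EEL EPB ENPOLAR", "-40 -30 60 -5"), path2)
  expect_equal(read_energy_table(path2)$frame, 0)

  path3 <- tempfile(fileext = ".csv")
  writeLines(c("VDWAALS,EEL,EPB", "-40,-30,60"), path3)
  expect_error(read_energy_table(path3), "ENPOLAR")

  path4 <- tempfile(fileext = ".csv")
  writeLines(c("VDWAALS,EEL,EPB,ENPOLAR", "-40,oops,60,-5"), path4)
  expect_error(read_energy_table(path4), "row 1.*EEL")
})

test_that("write_table is deterministic and round-trips values", {
  df <- data.frame(b = c(1.123456789e-3, 2), a = c("x", "y"))
  p1 <- tempfile(fileext = ".csv")
  p2 <- tempfile(fileext = ".csv")
  write_table(df, p1)
  write_table(df, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read.csv(p1)
  expect_equal(names(back), c("b", "a"))  # column order preserved
  expect_equal(back$b, df$b, tolerance = 1e-9)

  empty <- tempfile(fileext = ".csv")
  write_table(df[0, ], empty)
  expect_equal(readLines(empty), "\"b\",\"a\"")
})
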