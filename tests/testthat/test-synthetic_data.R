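test_that("generators are deterministic given the spec and seed", {
  c1 <- make_toy_complex(10, 3, seed = 1)
  c2 <- make_toy_complex(10, 3, seed = 1)
  expect_identical(c1, c2)
  expect_false(identical(c1, make_toy_complex(10, 3, seed = 2)))

  spec <- synthetic_spec(seed = 5, n_frames = 30)
  expect_identical(simulate_bound_trajectory(c1, spec),
                   simulate_bound_trajectory(c1, spec))
  expect_identical(simulate_energy_table(spec), simulate_energy_table(spec))
  rec <- make_toy_complex(8, 1, seed = 9)$structure
  expect_identical(
    simulate_pose_set(rec, c(0, 0, 0), c(24, 0, 0), spec),
    simulate_pose_set(rec, c(0, 0, 0), c(24, 0, 0), spec)
  )
})

test_that("toy complexes always carry a native contact and scale down to 2 atoms", {
  for (seed in 1:10) {
    cplx <- make_toy_complex(sample(1:20, 1), sample(1:5, 1), seed = seed)
    f0 <- coords(cplx$structure)
    d <- min(as.matrix(dist(f0))[cplx$receptor_atoms, cplx$ligand_atoms])
    expect_lte(d, 7)
  }
  tiny <- make_toy_complex(1, 1, seed = 3)
  traj <- Trajectory(tiny$structure, list(coords(tiny$structure)))
  np <- native_pairs(traj, tiny$receptor_atoms, tiny$ligand_atoms)
  expect_equal(stability_series(traj, np)$ss, 1)
})

test_that("bound trajectories stay stable: zero jitter gives SS = 1 throughout", {
  cplx <- make_toy_complex(10, 3, seed = 2)
  still <- synthetic_spec(seed = 2, n_frames = 50, jitter_sigma_A = 0)
  traj <- simulate_bound_trajectory(cplx, still)
  ss <- stability_series(
    traj, native_pairs(traj, cplx$receptor_atoms, cplx$ligand_atoms)
  )
  expect_true(all(ss$ss == 1))

  mild <- synthetic_spec(seed = 2, n_frames = 200, jitter_sigma_A = 0.3)
  traj2 <- simulate_bound_trajectory(cplx, mild)
  ss2 <- suppressWarnings(stability_series(
    traj2, native_pairs(traj2, cplx$receptor_atoms, cplx$ligand_atoms)
  ))
  expect_gte(mean_ss(ss2), 0.9)
  expect_error(
    simulate_bound_trajectory(cplx, synthetic_spec(seed = 1, exit_frame = 10L)),
    "exit_frame"
  )
})

test_that("unbinding trajectories clear every native pair after the drift", {
  cplx <- make_toy_complex(10, 3, seed = 4)
  spec <- synthetic_spec(seed = 4, n_frames = 100, jitter_sigma_A = 0.3,
                         exit_frame = 50L, drift_rate_A_per_frame = 1)
  traj <- simulate_unbinding_trajectory(cplx, spec)
  ss <- suppressWarnings(stability_series(
    traj, native_pairs(traj, cplx$receptor_atoms, cplx$ligand_atoms)
  ))
  # 15 A of displacement clears any <= 7 A pair plus jitter margin
  expect_true(all(ss$ss[ss$frame >= 65] == 0))
  expect_true(detect_exit(ss) >= 50 && detect_exit(ss) <= 70)

  no_drift <- synthetic_spec(seed = 4, n_frames = 100, exit_frame = 50L,
                             drift_rate_A_per_frame = 0)
  expect_error(simulate_unbinding_trajectory(cplx, no_drift), "drift")
  late <- synthetic_spec(seed = 4, n_frames = 100, exit_frame = 100L)
  expect_error(simulate_unbinding_trajectory(cplx, late), "exit_frame")
})

test_that("energy tables round-trip their drawn sums through disk and decompose", {
  spec <- synthetic_spec(seed = 10, n_frames = 100)
  es <- simulate_energy_table(spec)
  path <- tempfile(fileext = ".csv")
  write_table(as.data.frame(es), path)
  d <- decompose(read_energy_table(path))
  d0 <- decompose(es)
  expect_equal(d$dG_vdw, d0$dG_vdw, tolerance = 1e-6)
  expect_equal(d$dG_ele, d0$dG_ele, tolerance = 1e-6)
  expect_equal(d$dG_total, d0$dG_total, tolerance = 1e-6)
})

test_that("a zero-variance packing component makes the total track dG_ele exactly", {
  spec <- synthetic_spec(seed = 11, n_frames = 50, energy_sds = c(0, 1))
  d <- decompose(simulate_energy_table(spec))
  expect_equal(framewise_correlation(d$dG_total, d$dG_ele)$r, 1,
               tolerance = 1e-9)
})

test_that("variance dominance yields the expected correlation ordering", {
  wins <- 0L
  for (seed in 1:100) {
    spec <- synthetic_spec(seed = seed, n_frames = 100, energy_sds = c(10, 2))
    d <- decompose(simulate_energy_table(spec))
    rv <- framewise_correlation(d$dG_total, d$dG_vdw)$r
    re <- framewise_correlation(d$dG_total, d$dG_ele)$r
    if (rv > re) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("correlation targets are honoured and infeasible pairs rejected", {
  # a mutually consistent target pair for sds (10, 5):
  # (r_vt * sv)^2 - (r_et * se)^2 = sv^2 - se^2 holds for (0.95, sqrt(0.61))
  spec <- synthetic_spec(seed = 12, n_frames = 5000, energy_sds = c(10, 5),
                         target_corr_vdw_total = 0.95,
                         target_corr_ele_total = sqrt(0.61))
  d <- decompose(simulate_energy_table(spec))
  expect_equal(framewise_correlation(d$dG_total, d$dG_vdw)$r, 0.95,
               tolerance = 0.02)
  expect_equal(framewise_correlation(d$dG_total, d$dG_ele)$r, sqrt(0.61),
               tolerance = 0.05)
  bad <- synthetic_spec(seed = 12, energy_sds = c(10, 10),
                        target_corr_vdw_total = 0.99,
                        target_corr_ele_total = -0.99)
  expect_error(simulate_energy_table(bad), "determinant")
})

test_that("pose sets honour weights exactly and respect the separability guard", {
  rec <- make_toy_complex(8, 1, seed = 7)$structure
  spec <- synthetic_spec(seed = 7, n_poses = 200,
                         pose_weights = c(front = 0, back = 1, other = 0))
  ps <- simulate_pose_set(rec, c(0, 0, 0), c(24, 0, 0), spec)
  d_back <- vapply(ps$pose_coords,
                   function(m) sqrt(sum((m[1, ] - c(24, 0, 0))^2)),
                   numeric(1))
  expect_true(all(d_back <= 8))  # all back poses, within 4 sigma

  close_spec <- synthetic_spec(seed = 7, pose_sigma_A = 2)
  expect_error(simulate_pose_set(rec, c(0, 0, 0), c(5, 0, 0), close_spec),
               "apart")
})

test_that("a triplicate bound-vs-unbinding design recovers its construction", {
  # strong binder at one site, weak at the other, in triplicate
  cplx <- make_toy_complex(10, 3, seed = 30)
  rows <- list()
  for (site in c("front", "back")) {
    for (k in 1:3) {
      jitter <- if (site == "front") 0.3 else 1.6
      spec <- synthetic_spec(seed = 30 + k + 10 * (site == "back"),
                             n_frames = 60, jitter_sigma_A = jitter)
      traj <- simulate_bound_trajectory(cplx, spec)
      ss <- suppressWarnings(stability_series(
        traj, native_pairs(traj, cplx$receptor_atoms, cplx$ligand_atoms)
      ))
      w <- production_window(ss)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = "oct-pp", kr_type = "DM-ActKR", binding_site = site,
        replicate = k, value = w$ss, stringsAsFactors = FALSE
      )
    }
  }
  res <- grouped_comparison(do.call(rbind, rows), grouping = "by-binding-site")
  expect_equal(res$direction, 1)  # front-constructed advantage recovered
  expect_lt(res$p_value, 0.05)
})
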