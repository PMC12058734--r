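test_that("centre of mass is the mass-weighted mean position", {
  expect_equal(center_of_mass(matrix(c(1, 2, 3), 1, 3)), c(1, 2, 3))
  pts <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(center_of_mass(pts), c(1, 0, 0))
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(4, 0, 0)), c(1, 3)),
               c(3, 0, 0))
  expect_error(center_of_mass(pts, c(0, 0)), "total mass")
})

test_that("COM distance between chains is Euclidean", {
  beads <- tibble::tibble(
    bead = c("a1", "a2", "b1"), chain = c("A", "A", "B"),
    residue = 1:3, mass = c(1, 1, 2), radius = 0.2
  )
  xyz <- rbind(c(-1, 0, 0), c(1, 0, 0), c(3, 4, 0))
  expect_equal(com_distance(xyz, beads, "A", "B"), 5)
  expect_equal(com_distance(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                            beads, "A", "B"), 0)
  expect_error(com_distance(xyz, beads, "A", "C"), "selection error")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(5, 5, 5), 1, 3)), 0)
  pair <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(radius_of_gyration(pair), 1.5, tolerance = 1e-9)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(radius_of_gyration(cube), sqrt(3) / 2, tolerance = 1e-9)
})

test_that("Kabsch recovers exact transforms and excludes reflections", {
  set.seed(5)
  a <- matrix(rnorm(12), 4, 3)

  same <- kabsch_superpose(a, a)
  expect_equal(same$rotation, diag(3), tolerance = 1e-10)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)

  shifted <- sweep(a, 2, c(1, -2, 0.5), `+`)
  fit <- kabsch_superpose(shifted, a)
  expect_equal(fit$translation, c(-1, 2, -0.5), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  b <- a %*% t(rot90)
  fit90 <- kabsch_superpose(b, a)
  expect_equal(fit90$rotation %*% rot90, diag(3), tolerance = 1e-8)
  expect_equal(fit90$rmsd, 0, tolerance = 1e-8)

  # mirrored points: best proper rotation still has det +1
  mirrored <- a %*% diag(c(-1, 1, 1))
  fitm <- kabsch_superpose(mirrored, a)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-10)

  skinny <- cbind(1:5, 0, 0) + 0 # collinear
  expect_warning(kabsch_superpose(skinny, skinny), "collinear")
})

test_that("Kabsch RMSD agrees with the bio3d oracle", {
  set.seed(9)
  a <- matrix(rnorm(30), 10, 3)
  b <- a %*% t(random_rotation()) + matrix(rnorm(30, sd = 0.1), 10, 3)
  ours <- kabsch_superpose(b, a)$rmsd
  fitted <- suppressWarnings( # bio3d notes it is fitting on all positions
    bio3d::fit.xyz(fixed = as.vector(t(a)), mobile = as.vector(t(b)))
  )
  oracle <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(ours, oracle, tolerance = 1e-6)
})

test_that("RMSF is zero for static and rigidly moving trajectories", {
  traj <- static_two_chain_traj(n_frames = 4)
  expect_equal(max(rmsf(traj)$rmsf), 0, tolerance = 1e-10)

  # rigid-body translation: zero after superposition
  moving <- traj
  for (f in seq_len(4)) {
    moving$coords[f, , ] <- sweep(traj$coords[f, , ], 2, c(f, 2 * f, 0), `+`)
  }
  expect_equal(max(rmsf(moving, superpose = TRUE)$rmsf), 0, tolerance = 1e-8)
  expect_gt(max(rmsf(moving, superpose = FALSE)$rmsf), 0)

  single <- cg_trajectory(traj$coords[1, , , drop = FALSE], traj$beads)
  expect_error(rmsf(single), "at least 2 frames")
})

test_that("an alternating site has RMSF d/2 without superposition", {
  d <- 0.8
  base <- matrix(seq_len(12) / 5, 4, 3)
  coords <- array(NA_real_, dim = c(2, 4, 3))
  coords[1, , ] <- base
  coords[2, , ] <- base
  coords[1, 4, 1] <- base[4, 1] - d / 2
  coords[2, 4, 1] <- base[4, 1] + d / 2
  beads <- tibble::tibble(
    bead = paste0("b", 1:4), chain = "A", residue = 1:4,
    mass = 72, radius = 0.235
  )
  traj <- cg_trajectory(coords, beads)
  out <- rmsf(traj, superpose = FALSE)
  expect_equal(out$rmsf[out$residue == 4], d / 2 * 10, tolerance = 1e-10)
  expect_equal(out$rmsf[out$residue == 1], 0, tolerance = 1e-10)
})

test_that("SASA matches the analytic sphere and is additive when disjoint", {
  r <- 0.235
  probe <- 0.14
  analytic <- 4 * pi * (r + probe)^2
  one <- shrake_rupley_sasa(matrix(0, 1, 3), r, probe, 960)
  expect_lt(abs(one - analytic) / analytic, 0.01)

  # separation beyond 2(r+probe): no occlusion, exact additivity
  two <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(1.0, 0, 0)), r, probe, 960)
  expect_equal(two, 2 * one, tolerance = 1e-12)

  # bead buried inside a large sphere contributes nothing
  buried <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(0.05, 0, 0)),
                               c(1.0, 0.1), probe, 960)
  big_alone <- shrake_rupley_sasa(matrix(0, 1, 3), 1.0, probe, 960)
  expect_equal(buried, big_alone, tolerance = 1e-12)

  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), r, probe = 0), "probe")
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), r, n_points = 8), "n_points")
})

test_that("SASA quadrature error shrinks as points double", {
  # two slightly overlapping spheres: quadrature converges to a stable value
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  vals <- vapply(c(240, 480, 960, 1920), function(n) {
    shrake_rupley_sasa(xyz, 0.235, 0.14, n)
  }, numeric(1))
  ref <- shrake_rupley_sasa(xyz, 0.235, 0.14, 7680)
  errs <- abs(vals - ref)
  expect_lt(errs[[3]], errs[[1]] + 1e-9)
  expect_lt(errs[[4]] / ref, 0.005)
})

test_that("Rg, COMD and superposed RMSD are rigid-motion invariant", {
  set.seed(17)
  sim <- make_assembly_traj(trajectory_plan(
    n_frames = 5, n_beads_per_chain = 8, jitter_sigma = 0.02, seed = 23
  ))
  traj <- sim$traj
  moved <- traj
  for (f in seq_len(n_frames(traj))) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 2)
    moved$coords[f, , ] <- sweep(traj$coords[f, , ] %*% t(rot), 2, shift, `+`)
  }
  for (f in c(1L, 3L, 5L)) {
    expect_equal(
      radius_of_gyration(frame_coords(moved, f), moved$beads$mass),
      radius_of_gyration(frame_coords(traj, f), traj$beads$mass),
      tolerance = 1e-9
    )
    expect_equal(
      com_distance(frame_coords(moved, f), moved$beads, "A", "B"),
      com_distance(frame_coords(traj, f), traj$beads, "A", "B"),
      tolerance = 1e-9
    )
  }
  expect_equal(rmsd_series(moved)$rmsd, rmsd_series(traj)$rmsd,
               tolerance = 1e-7)
  expect_equal(rmsf(moved)$rmsf, rmsf(traj)$rmsf, tolerance = 1e-7)
})
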