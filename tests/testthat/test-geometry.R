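test_that("dipole moment follows the closed form 4.8032 q d", {
  d <- dipole_moment(make_dumbbell(0.5, 2))
  expect_equal(d$magnitude, 4.8032, tolerance = 1e-9)
  expect_equal(d$vector, c(0, 0, 4.8032), tolerance = 1e-9)
  expect_equal(d$angle_to_normal, 0, tolerance = 1e-9)
  expect_equal(d$net_charge, 0, tolerance = 1e-12)

  expect_equal(dipole_moment(make_dumbbell(1e-12, 2))$magnitude, 0,
               tolerance = 1e-9)
  none <- molecular_model(data.frame(x = 1:3, y = 0, z = 0))
  expect_equal(dipole_moment(none)$magnitude, 0)
})

test_that("neutral-system dipole is origin-independent, charged is not", {
  b <- random_body(40, seed = 31)
  b$atoms$charge <- b$atoms$charge - mean(b$atoms$charge)  # neutralize
  mu0 <- dipole_moment(b, origin = "center_of_mass")$vector
  set.seed(99)
  for (k in 1:5) {
    o <- runif(3, -50, 50)
    expect_equal(dipole_moment(b, origin = o)$vector, mu0,
                 tolerance = 1e-9)
  }
  charged <- random_body(40, seed = 31)
  charged$atoms$charge <- charged$atoms$charge + 0.1
  m1 <- dipole_moment(charged, origin = c(0, 0, 0))$vector
  m2 <- dipole_moment(charged, origin = c(10, 0, 0))$vector
  expect_gt(max(abs(m1 - m2)), 1e-3)
})

test_that("dipole magnitude is linear in the charges", {
  b <- random_body(40, seed = 32)
  mu1 <- dipole_moment(b)
  b2 <- b
  b2$atoms$charge <- -3 * b$atoms$charge
  expect_equal(dipole_moment(b2)$magnitude, 3 * mu1$magnitude,
               tolerance = 1e-9)
})

test_that("trajectory statistics collapse for identical frames and scale", {
  frames <- rep(list(make_dumbbell(0.5, 2)), 5)
  st <- trajectory_dipole_stats(frames)
  expect_equal(st$angular_spread, 0, tolerance = 1e-9)
  expect_equal(st$magnitude_sd, 0, tolerance = 1e-12)
  expect_equal(st$magnitude_mean, 4.8032, tolerance = 1e-9)
  expect_equal(st$mean_direction, c(0, 0, 1), tolerance = 1e-9)

  traj <- make_vmf_dipole_trajectory(50, kappa = 50, seed = 2)
  st1 <- trajectory_dipole_stats(traj)
  doubled <- lapply(traj, function(f) {
    f$atoms$charge <- 2 * f$atoms$charge
    f
  })
  st2 <- trajectory_dipole_stats(doubled)
  expect_equal(st2$magnitude_mean, 2 * st1$magnitude_mean, tolerance = 1e-9)
  expect_equal(st2$angular_spread, st1$angular_spread, tolerance = 1e-12)

  bad <- c(traj[1:2], list(make_patchy_sphere(n_atoms = 20)))
  expect_error(trajectory_dipole_stats(bad), "atom counts")
})

test_that("vMF trajectories reproduce the closed-form angular spread", {
  traj <- make_vmf_dipole_trajectory(1000, kappa = 100, seed = 1)
  st <- trajectory_dipole_stats(traj)
  expect_equal(st$angular_spread, vmf_expected_spread(100), tolerance = 0.2)
  # near-degenerate concentration pins the direction
  tight <- make_vmf_dipole_trajectory(100, kappa = 1e6, seed = 1)
  expect_lt(trajectory_dipole_stats(tight)$angular_spread, 0.5)
})

test_that("vMF concentration is recovered within 20% median relative error", {
  err <- vapply(1:50, function(seed) {
    traj <- make_vmf_dipole_trajectory(1000, kappa = 100, seed = seed)
    mu <- t(vapply(traj, function(f) dipole_moment(f)$vector, numeric(3)))
    kap <- vmf_estimate_kappa(mu / sqrt(rowSums(mu^2)))
    abs(kap - 100) / 100
  }, numeric(1))
  expect_lt(median(err), 0.2)
})

test_that("surface distance uses the selection centroid and reference plane", {
  s <- build_sam_surface(surface_spec(nx = 6, ny = 6))
  one <- molecular_model(data.frame(x = 5, y = 5, z = s$top_z + 12),
                         selections = list(probe = 1L))
  expect_equal(surface_distance(one, "probe", s), 12, tolerance = 1e-12)

  two <- molecular_model(data.frame(x = c(0, 1), y = 0,
                                    z = s$top_z + c(10, 14)),
                         selections = list(pair = 1:2))
  expect_equal(surface_distance(two, "pair", s), 12, tolerance = 1e-12)

  # invariance under in-plane translation
  shifted <- two
  coords(shifted) <- coords(two) + rep(c(7, -3, 0), each = 2)
  expect_equal(surface_distance(shifted, "pair", s),
               surface_distance(two, "pair", s), tolerance = 1e-12)

  # au_top reference differs from sam_top by the SAM height
  expect_equal(surface_distance(two, "pair", s, reference = "au_top"),
               12 + s$top_z, tolerance = 1e-12)

  expect_error(surface_distance(two, "nope", s), "unknown selection")

  # consistency with the placement contract: the lowest atom ends at gap
  b <- random_body(20, seed = 44)
  b$selections$lowest <- which.min(coords(b)[, 3])
  p <- place_above(b, s, gap = 5)
  p$selections$lowest <- which.min(coords(p)[, 3])
  expect_equal(surface_distance(p, "lowest", s), 5, tolerance = 1e-9)
})

test_that("Kabsch RMSD vanishes for rigid copies and is symmetric", {
  b <- random_body(25, seed = 51)
  expect_equal(kabsch_rmsd(b, b), 0, tolerance = 1e-9)
  moved <- rotate_model(b, 73, 211)
  coords(moved) <- coords(moved) + rep(c(5, -3, 11), each = n_atoms(b))
  expect_lt(kabsch_rmsd(b, moved), 1e-9)

  other <- random_body(25, seed = 52)
  expect_equal(kabsch_rmsd(b, other), kabsch_rmsd(other, b),
               tolerance = 1e-9)
  expect_gte(kabsch_rmsd(b, other), 0)
  expect_error(kabsch_rmsd(b, random_body(10, seed = 1)), "counts differ")
})

test_that("Kabsch RMSD matches an exhaustive rotation-grid oracle", {
  # 4-point toys; oracle scans Euler angles on a grid, then polishes with a
  # generic optimiser -- independent of the SVD superposition route.
  rmsd_at <- function(angles, xa, xb) {
    cz <- function(g) matrix(c(cos(g), -sin(g), 0,
                               sin(g), cos(g), 0, 0, 0, 1), 3, 3, TRUE)
    cy <- function(g) matrix(c(cos(g), 0, sin(g), 0, 1, 0,
                               -sin(g), 0, cos(g)), 3, 3, TRUE)
    r <- cz(angles[1]) %*% cy(angles[2]) %*% cz(angles[3])
    xr <- xb %*% t(r)
    xr <- sweep(xr, 2, colMeans(xr) - colMeans(xa))
    sqrt(mean(rowSums((xa - xr)^2)))
  }
  set.seed(7)
  for (rep in 1:3) {
    xa <- matrix(rnorm(12, sd = 3), 4, 3)
    xb <- matrix(rnorm(12, sd = 3), 4, 3)
    grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 25)[-25],
                                  b = seq(0, pi, length.out = 13),
                                  c = seq(0, 2 * pi, length.out = 25)[-25]))
    vals <- apply(grid, 1, rmsd_at, xa = xa, xb = xb)
    best <- optim(grid[which.min(vals), ], rmsd_at, xa = xa, xb = xb,
                  method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))$value
    got <- kabsch_rmsd(molecular_model(as.data.frame(`colnames<-`(xa, c("x", "y", "z")))),
                       molecular_model(as.data.frame(`colnames<-`(xb, c("x", "y", "z")))))
    expect_equal(got, best, tolerance = 1e-3)
    expect_lte(got, best + 1e-6)  # superposition is never worse than the grid
  }
})

test_that("hexagonal-packing coverage matches the closed form and scaling", {
  cov9 <- coverage_hex_packing(9)
  expect_equal(cov9$molar_coverage, 2.37, tolerance = 0.005)
  expect_equal(cov9$molar_coverage,
               1e12 / (6.02214076e23 * sqrt(3) / 2 * (9e-7)^2),
               tolerance = 1e-12)
  expect_equal(coverage_hex_packing(4.5)$molar_coverage,
               4 * cov9$molar_coverage, tolerance = 1e-9)
  expect_lt(coverage_hex_packing(1e6)$molar_coverage, 1e-9)

  with_mass <- coverage_hex_packing(9, molecular_weight = 170000)
  expect_equal(with_mass$molar_coverage,
               with_mass$mass_coverage / 170000 * 1e3, tolerance = 1e-9)
})

test_that("de Feijter coverage matches the closed form", {
  est <- coverage_de_feijter(7, 1.41, 1.33, 0.18, 170000)
  expect_equal(est$molar_coverage, 1.83, tolerance = 0.005)
  expect_equal(est$mass_coverage, 311.1, tolerance = 0.05)
  expect_equal(coverage_de_feijter(0, 1.41, 1.33, 0.18, 170000)$molar_coverage,
               0)
  expect_equal(coverage_de_feijter(7, 1.41, 1.33, 0.36, 170000)$molar_coverage,
               est$molar_coverage / 2, tolerance = 1e-9)
  expect_error(coverage_de_feijter(7, 1.30, 1.33, 0.18, 170000),
               "nonphysical")
})
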