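test_that("rotation is rigid and follows the R_y(psi) R_x(theta) convention", {
  b <- random_body(50, seed = 11)
  expect_equal(coords(rotate_model(b, 0, 0)), coords(b), tolerance = 1e-12)

  # half-turn about x maps COM + (0,1,0) to COM - (0,1,0)
  two <- molecular_model(data.frame(x = c(0, 0), y = c(0, 2), z = c(0, 0)))
  cog <- center_of_geometry(two)
  r <- rotate_model(two, 180, 0)
  expect_equal(unname(coords(r)[2, ]), unname(cog + c(0, -1, 0)),
               tolerance = 1e-12)

  # rigidity: pairwise distance matrix preserved for arbitrary angles
  for (ang in list(c(37, 113), c(250, 10), c(180, 180))) {
    d0 <- dist(coords(b))
    d1 <- dist(coords(rotate_model(b, ang[1], ang[2])))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }

  # rotation matrices are proper orthonormal
  r <- rotation_matrix(37, 113)
  expect_equal(t(r) %*% r, diag(3), tolerance = 1e-9)
  expect_equal(det(r), 1, tolerance = 1e-9)
})

test_that("placement sets the protein-SAM gap exactly and is idempotent", {
  s <- build_sam_surface(surface_spec(nx = 10, ny = 10))
  b <- random_body(30, seed = 3)
  p <- place_above(b, s, gap = 5)
  expect_equal(min(coords(p)[, 3]) - s$top_z, 5, tolerance = 1e-9)
  p0 <- place_above(b, s, gap = 1e-12)
  expect_equal(min(coords(p0)[, 3]), s$top_z, tolerance = 1e-9)
  expect_equal(coords(place_above(p, s, gap = 5)), coords(p),
               tolerance = 1e-12)
  wide <- random_body(30, seed = 3, spread = 60)
  expect_warning(place_above(wide, s, gap = 5), "footprint")
})

test_that("energy kernel reproduces closed-form pair energies", {
  cfg <- scan_config(cutoff = Inf)
  a <- molecular_model(data.frame(x = 0, y = 0, z = 0, charge = 1))
  b <- molecular_model(data.frame(x = 3.320636, y = 0, z = 0, charge = 1))
  expect_equal(interaction_energy(a, b, cfg), 100.00, tolerance = 1e-4)

  # LJ pair at r = Rmin gives exactly -eps_ij
  la <- molecular_model(data.frame(x = 0, y = 0, z = 0, charge = 0,
                                   lj_epsilon = 0.2, lj_rmin_half = 1.6))
  lb <- molecular_model(data.frame(x = 3.5, y = 0, z = 0, charge = 0,
                                   lj_epsilon = 0.45, lj_rmin_half = 1.9))
  expect_equal(interaction_energy(la, lb, cfg), -sqrt(0.2 * 0.45),
               tolerance = 1e-12)

  nothing <- molecular_model(data.frame(x = c(0, 1), y = 0, z = 0))
  expect_equal(interaction_energy(nothing, nothing, cfg), 0)

  overlap <- molecular_model(data.frame(x = 0, y = 0, z = 0, charge = -1))
  expect_error(interaction_energy(a, overlap, cfg), "zero distance")
})

test_that("energy kernel equals the brute-force double-loop oracle", {
  cfg_inf <- scan_config(cutoff = Inf)
  a <- random_body(30, seed = 1)
  b <- random_body(40, seed = 2)
  coords(b) <- coords(b) + 25  # separate the bodies
  expect_equal(interaction_energy(a, b, cfg_inf), oracle_energy(a, b),
               tolerance = 1e-8)

  # also with truncation, and at a larger size
  cfg_cut <- scan_config(cutoff = 30)
  expect_equal(interaction_energy(a, b, cfg_cut),
               oracle_energy(a, b, cutoff = 30), tolerance = 1e-8)
  big_a <- random_body(400, seed = 5, spread = 15)
  big_b <- random_body(600, seed = 6, spread = 15)
  coords(big_b) <- coords(big_b) + c(0, 0, 40)
  expect_equal(interaction_energy(big_a, big_b, cfg_inf),
               oracle_energy(big_a, big_b), tolerance = 1e-8)
})

test_that("Coulomb part scales as 1/dielectric", {
  a <- random_body(20, seed = 21)
  b <- random_body(20, seed = 22)
  coords(b) <- coords(b) + 25
  a$atoms$lj_epsilon <- 0
  b$atoms$lj_epsilon <- 0
  e1 <- interaction_energy(a, b, scan_config(cutoff = Inf, dielectric = 1))
  e2 <- interaction_energy(a, b, scan_config(cutoff = Inf, dielectric = 2))
  expect_equal(e2, e1 / 2, tolerance = 1e-12)
})

test_that("default scan covers a deterministic 36 x 36 half-open grid", {
  s <- build_sam_surface(surface_spec(nx = 4, ny = 4))
  b <- make_dumbbell(0.2, 2, lj_epsilon = 0.1, lj_rmin_half = 2)
  l <- scan_orientations(b, s)
  expect_equal(dim(l$energies), c(36L, 36L))
  expect_equal(l$theta_values, seq(0, 350, by = 10))
  expect_equal(l$psi_values, seq(0, 350, by = 10))
  expect_true(all(is.finite(l$energies)))
  l2 <- scan_orientations(b, s)
  expect_identical(l$energies, l2$energies)

  # uncharged, LJ-less body: identically zero landscape
  ghost <- molecular_model(data.frame(x = runif(10), y = runif(10),
                                      z = runif(10)))
  lg <- scan_orientations(ghost, s, scan_config(theta_step = 90,
                                                psi_step = 90))
  expect_true(all(lg$energies == 0))
})

test_that("scan energies match the oracle energy at the scan's placement", {
  s <- build_sam_surface(surface_spec(nx = 6, ny = 6))
  b <- make_patchy_sphere(n_atoms = 60, radius = 8)
  cfg <- scan_config(theta_step = 120, psi_step = 120, cutoff = Inf)
  l <- scan_orientations(b, s, cfg)
  smod <- surface_as_model(s)
  for (i in seq_along(l$theta_values)) {
    for (j in seq_along(l$psi_values)) {
      posed <- place_above(rotate_model(b, l$theta_values[i],
                                        l$psi_values[j]), s, cfg$gap)
      expect_equal(l$energies[i, j], oracle_energy(posed, smod),
                   tolerance = 1e-8)
    }
  }
})

test_that("patchy sphere adsorbs cap-down on the +8 e surface", {
  ps <- make_patchy_sphere()
  # discrete 8%-protonated slab (the default surface chemistry at 10 x 10)
  s <- build_sam_surface(surface_spec(nx = 10, ny = 10,
                                      protonation_fraction = 0.08))
  l <- scan_orientations(ps, s)
  idx <- which(l$energies == min(l$energies), arr.ind = TRUE)
  th <- l$theta_values[idx[1]]
  psv <- l$psi_values[idx[2]]
  capdir <- drop(rotation_matrix(th, psv) %*% c(0, 0, 1))
  expect_lt(capdir[3], -0.9)  # cap rotated to face the surface

  # scan minimum agrees with the brute-force oracle at the same placements
  smod <- surface_as_model(s)
  probe <- rbind(c(th, psv), c(0, 180), c(180, 0), c(0, 0), c(90, 90))
  e_probe <- apply(probe, 1, function(ang) {
    posed <- place_above(rotate_model(ps, ang[1], ang[2]), s, 5)
    oracle_energy(posed, smod, cutoff = 30)
  })
  expect_equal(min(l$energies), e_probe[1], tolerance = 1e-8)
  expect_true(all(e_probe[1] <= e_probe + 1e-9))

  # on a laterally homogeneous slab of the same net charge the idealized
  # symmetric optimum is recovered exactly: (0, 180) or (180, 0)
  hs <- build_sam_surface(surface_spec(nx = 10, ny = 10,
                                       protonation_fraction = 1,
                                       headgroup_charge_protonated = 0.08))
  lh <- scan_orientations(ps, hs)
  ih <- which(lh$energies == min(lh$energies), arr.ind = TRUE)
  best <- c(lh$theta_values[ih[1]], lh$psi_values[ih[2]])
  expect_true(identical(best, c(0, 180)) || identical(best, c(180, 0)))
})

test_that("lateral shift by one lattice vector changes energies < 1%", {
  # idealized laterally homogeneous slab of the default geometry and net
  # charge: one lattice vector is an exact symmetry away from the edges
  s <- build_sam_surface(surface_spec(protonation_fraction = 1,
                                      headgroup_charge_protonated = 0.08))
  b <- make_patchy_sphere(n_atoms = 80, radius = 10)
  smod <- surface_as_model(s)
  for (ang in list(c(0, 180), c(90, 0))) {
    posed <- place_above(rotate_model(b, ang[1], ang[2]), s, 5)
    e0 <- interaction_energy(posed, smod)
    shifted <- posed
    coords(shifted) <- coords(posed) + rep(c(s$spec$thiol_spacing, 0, 0),
                                           each = n_atoms(posed))
    e1 <- interaction_energy(shifted, smod)
    expect_lt(abs(e1 - e0) / abs(e0), 0.01)
  }
})

test_that("greedy minima selection recovers planted basins deterministically", {
  l <- make_two_basin_landscape()
  m <- select_minima(l, k = 2)
  expect_length(m, 2L)
  expect_equal(c(m[[1]]$theta, m[[1]]$psi), c(60, 300))
  expect_equal(c(m[[2]]$theta, m[[2]]$psi), c(250, 100))

  # k = 1 is the matrix argmin
  m1 <- select_minima(l, k = 1)[[1]]
  expect_equal(m1$energy, min(l$energies))

  # selected poses always honour the separation
  for (seed in c(1, 5, 9)) {
    mm <- select_minima(make_two_basin_landscape(noise_sd = 1, seed = seed),
                        k = 2)
    expect_gte(tor_cheb(mm[[1]]$theta, mm[[1]]$psi,
                        mm[[2]]$theta, mm[[2]]$psi), 30)
  }

  # a grid too small for the separation returns fewer poses with a warning
  tiny <- energy_landscape(c(0, 10), c(0, 10),
                           matrix(c(1, 2, 3, 4), 2),
                           config = scan_config(theta_step = 10,
                                                psi_step = 10))
  expect_warning(few <- select_minima(tiny, k = 2, separation = 30),
                 "separation")
  expect_length(few, 1L)
})

test_that("planted basins are recovered in at least 95% of noisy landscapes", {
  centers <- rbind(c(60, 300), c(250, 100))
  hits <- 0L
  for (seed in 1:100) {
    m <- select_minima(make_two_basin_landscape(noise_sd = 0.8, seed = seed),
                       k = 2)
    got <- cbind(vapply(m, `[[`, numeric(1), "theta"),
                 vapply(m, `[[`, numeric(1), "psi"))
    ok <- all(apply(centers, 1, function(cc)
      any(tor_cheb(got[, 1], got[, 2], cc[1], cc[2]) <= 10)))
    hits <- hits + ok
  }
  expect_gte(hits, 95L)
})

test_that("field re-ranking follows the dipole-field closed form", {
  d <- make_dumbbell(0.5, 2)
  l0 <- energy_landscape(seq(0, 350, 10), seq(0, 350, 10),
                         matrix(0, 36, 36))
  dip <- scan_dipoles(d, l0)

  # weight 0 leaves the landscape untouched
  f0 <- field_spec(field_z = 0.01, applied_potential = 0, weight = 0)
  expect_equal(field_rerank(l0, dip, f0)$energies, l0$energies)

  # above the PZC the field points along +z and the score is minimized
  # where the dipole is parallel to it; the term is -mu_z * E_z (converted)
  f <- field_spec(field_z = 0.01, applied_potential = 0, weight = 1)
  ranked <- field_rerank(l0, dip, f)
  imin <- which(ranked$energies == min(ranked$energies), arr.ind = TRUE)[1, ]
  expect_equal(dip[imin[1], imin[2], 3], max(dip[, , 3]), tolerance = 1e-9)
  expect_equal(min(ranked$energies),
               -max(dip[, , 3]) * 0.01 * 23.060548 / 4.8032,
               tolerance = 1e-9)

  # below the PZC the field flips and the opposite orientation wins
  fneg <- field_spec(field_z = 0.01, applied_potential = -0.34, weight = 1)
  ranked2 <- field_rerank(l0, dip, fneg)
  imin2 <- which(ranked2$energies == min(ranked2$energies),
                 arr.ind = TRUE)[1, ]
  expect_equal(dip[imin2[1], imin2[2], 3], min(dip[, , 3]), tolerance = 1e-9)
  expect_equal(ranked2$energies, -ranked$energies, tolerance = 1e-12)

  expect_error(field_rerank(l0, NULL, f), "dipole")
})

test_that("landscape CSV round-trips through the long format", {
  l <- make_two_basin_landscape(noise_sd = 0.3, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_landscape_csv(l, f)
  expect_equal(read.csv(f)[1, ],
               data.frame(theta_deg = 0, psi_deg = 0,
                          energy_kcal_mol = l$energies[1, 1]),
               tolerance = 1e-12)
  l2 <- read_landscape_csv(f)
  expect_equal(l2$energies, l$energies, tolerance = 1e-12)
  expect_equal(l2$theta_values, l$theta_values)
})

test_that("scan configuration rejects invalid parameters", {
  expect_error(scan_config(theta_step = 7), "divide 360")
  expect_error(scan_config(gap = 0), "gap")
  expect_error(scan_config(dielectric = 0.5), "dielectric")
  expect_error(scan_config(cutoff = -3), "cutoff")
})
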