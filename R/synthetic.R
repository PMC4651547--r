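#' Toy dumbbell with a known analytic dipole
#'
#' Two atoms (+q, -q) on the z axis, centre of mass at the origin, so the
#' dipole is exactly `4.8032 * q * separation` Debye along +z and the net
#' charge is zero.
#'
#' @param q charge magnitude in e.
#' @param separation inter-atom distance in Å (> 0).
#' @param lj_epsilon,lj_rmin_half optional Lennard-Jones parameters for both
#'   atoms (default: none).
#' @return a [molecular_model()].
#' @export
make_dumbbell <- function(q, separation, lj_epsilon = 0, lj_rmin_half = 0) {
  stopifnot(separation > 0)
  molecular_model(data.frame(
    atom_name = c("DP", "DM"), element = "C", residue_name = "DUM",
    residue_number = 1L, chain_id = "A",
    x = 0, y = 0, z = c(separation / 2, -separation / 2),
    charge = c(q, -q),
    lj_epsilon = lj_epsilon, lj_rmin_half = lj_rmin_half,
    tags = "", stringsAsFactors = FALSE),
    name = "dumbbell")
}

#' Patchy-sphere toy protein
#'
#' A quasi-uniform spherical shell of pseudo-atoms (Fibonacci lattice).
#' Atoms within `cap_half_angle` of +z share `cap_charge` equally, forming
#' a controllable charge patch; everything else is neutral.  All atoms get
#' small identical Lennard-Jones parameters so electrostatics dominates.
#' Against an oppositely charged surface the known preferred orientation
#' turns the cap toward the surface — the ground truth for scan tests.
#'
#' @param n_atoms number of shell atoms (>= 10).
#' @param radius shell radius in Å.
#' @param cap_half_angle half-angle of the charged cap in degrees
#'   (180 = uniformly charged sphere).
#' @param cap_charge total charge of the cap in e.
#' @param seed kept for interface symmetry; the lattice is deterministic.
#' @param lj_epsilon,lj_rmin_half per-atom Lennard-Jones parameters.
#' @return a [molecular_model()] with a `"cap"` selection.
#' @export
make_patchy_sphere <- function(n_atoms = 200L, radius = 15,
                               cap_half_angle = 60, cap_charge = -1,
                               seed = 1L, lj_epsilon = 0.1,
                               lj_rmin_half = 2.0) {
  stopifnot(n_atoms >= 10)
  i <- seq_len(n_atoms) - 1L
  z <- 1 - (2 * i + 1) / n_atoms
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  pos <- radius * cbind(rho * cos(phi), rho * sin(phi), z)
  polar <- acos(pmin(1, pmax(-1, z))) * 180 / pi
  cap <- which(polar <= cap_half_angle)
  charge <- numeric(n_atoms)
  if (length(cap)) charge[cap] <- cap_charge / length(cap)
  molecular_model(data.frame(
    atom_name = "C", element = "C", residue_name = "TOY",
    residue_number = seq_len(n_atoms), chain_id = "A",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = charge, lj_epsilon = lj_epsilon,
    lj_rmin_half = lj_rmin_half, tags = "",
    stringsAsFactors = FALSE),
    name = "patchy_sphere",
    selections = list(cap = cap))
}

#' Synthetic two-basin energy landscape
#'
#' Two wrapped negative Gaussian wells on the (theta, psi) torus plus
#' optional seeded Gaussian noise, on the default 36 x 36 grid.  With the
#' centres on grid points and modest noise the planted minima are the
#' ground truth that [select_minima()] must recover.
#'
#' @param basin_centers list of two degree pairs `c(theta, psi)`.
#' @param depths well depths in kcal/mol (positive numbers).
#' @param width Gaussian width in degrees.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed noise seed.
#' @param theta_step,psi_step grid steps in degrees.
#' @return an [energy_landscape()].
#' @export
make_two_basin_landscape <- function(basin_centers = list(c(60, 300),
                                                          c(250, 100)),
                                     depths = c(10, 8), width = 15,
                                     noise_sd = 0, seed = 1L,
                                     theta_step = 10, psi_step = 10) {
  stopifnot(length(basin_centers) == 2, length(depths) == 2)
  tv <- seq(0, 360 - theta_step, by = theta_step)
  pv <- seq(0, 360 - psi_step, by = psi_step)
  grid_t <- matrix(tv, length(tv), length(pv))
  grid_p <- matrix(pv, length(tv), length(pv), byrow = TRUE)
  e <- matrix(0, length(tv), length(pv))
  for (k in 1:2) {
    d2 <- ang_dist(grid_t, basin_centers[[k]][1])^2 +
      ang_dist(grid_p, basin_centers[[k]][2])^2
    e <- e - depths[k] * exp(-d2 / (2 * width^2))
  }
  if (noise_sd > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    e <- e + matrix(stats::rnorm(length(e), sd = noise_sd), nrow(e))
  }
  energy_landscape(tv, pv, e,
                   config = scan_config(theta_step = theta_step,
                                        psi_step = psi_step),
                   provenance = list(generator = "two_basin",
                                     centers = basin_centers,
                                     depths = depths, width = width,
                                     noise_sd = noise_sd, seed = seed))
}

# von Mises-Fisher sampler on the unit sphere (d = 3), standard inversion:
# the cosine w of the polar angle about the mean has density prop. to
# exp(kappa * w); its CDF inverts in closed form.
rvmf <- function(n, mean_direction, kappa) {
  stopifnot(kappa > 0)
  mu <- mean_direction / sqrt(sum(mean_direction^2))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  v <- cbind(s * cos(phi), s * sin(phi), w)
  # rotate +z onto mu
  if (all(abs(mu - c(0, 0, 1)) < 1e-12)) return(v)
  if (all(abs(mu + c(0, 0, 1)) < 1e-12)) return(v %*% diag(c(1, -1, -1)))
  axis <- c(-mu[2], mu[1], 0)
  axis <- axis / sqrt(sum(axis^2))
  ang <- acos(mu[3])
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
  v %*% t(r)
}

#' Dipole pseudo-trajectory with von Mises-Fisher directional scatter
#'
#' Each frame is a dumbbell of fixed dipole magnitude whose axis is drawn
#' from a von Mises-Fisher distribution about `mean_direction` with
#' concentration `kappa` — a directional-noise stand-in for the dipole
#' fluctuation seen along an MD trajectory.  Larger `kappa` means a more
#' tightly pinned dipole direction.
#'
#' @param n_frames number of frames (>= 2).
#' @param mean_direction mean dipole direction (any nonzero 3-vector).
#' @param kappa vMF concentration (> 0).
#' @param magnitude dipole magnitude in Debye (exact in every frame).
#' @param seed RNG seed (caller's RNG state is preserved).
#' @param separation dumbbell length in Å.
#' @return list of [molecular_model()] frames.
#' @export
make_vmf_dipole_trajectory <- function(n_frames, mean_direction = c(0, 0, 1),
                                       kappa = 100, magnitude = 480.32,
                                       seed = 1L, separation = 2) {
  stopifnot(n_frames >= 2, kappa > 0)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  axes <- rvmf(n_frames, mean_direction, kappa)
  q <- magnitude / (EA_TO_DEBYE * separation)
  lapply(seq_len(n_frames), function(f) {
    ax <- axes[f, ]
    molecular_model(data.frame(
      atom_name = c("DP", "DM"), element = "C", residue_name = "DUM",
      residue_number = 1L, chain_id = "A",
      x = c(ax[1], -ax[1]) * separation / 2,
      y = c(ax[2], -ax[2]) * separation / 2,
      z = c(ax[3], -ax[3]) * separation / 2,
      charge = c(q, -q), lj_epsilon = 0, lj_rmin_half = 0,
      tags = "", stringsAsFactors = FALSE),
      name = sprintf("vmf_frame_%d", f))
  })
}

#' Closed-form expected angular spread of a vMF sample
#'
#' For concentration `kappa` on the sphere the expected mean resultant
#' length is `A(kappa) = coth(kappa) - 1/kappa`; the corresponding circular
#' standard deviation is `sqrt(-2 log A(kappa))`, returned in degrees.
#' Used as the independent oracle for spread-recovery tests.
#'
#' @param kappa vMF concentration (> 0).
#' @return expected angular spread in degrees.
#' @export
vmf_expected_spread <- function(kappa) {
  a <- 1 / tanh(kappa) - 1 / kappa
  sqrt(-2 * log(a)) * 180 / pi
}

#' Moment estimator of the vMF concentration
#'
#' Banerjee's approximation `kappa_hat = Rbar (3 - Rbar^2) / (1 - Rbar^2)`
#' from the mean resultant length of a sample of unit directions.
#'
#' @param directions n x 3 matrix of unit vectors.
#' @return estimated concentration.
#' @export
vmf_estimate_kappa <- function(directions) {
  rbar <- sqrt(sum(colMeans(directions)^2))
  rbar * (3 - rbar^2) / (1 - rbar^2)
}
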