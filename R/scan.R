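#' Configuration of an orientation scan
#'
#' Defaults follow the coarse screening protocol: 10 degree angular steps in
#' both angles (a 36 x 36 grid over \[0, 360) x \[0, 360)), a 5 Å gap
#' between the lowest protein atom and the topmost SAM heavy atom, in vacuo
#' electrostatics (relative dielectric 1), a plain 30 Å cutoff, and
#' selection of the two most favourable, mutually separated orientations.
#'
#' @param theta_step,psi_step angular steps in degrees; must divide 360.
#' @param gap protein-SAM gap in Å (> 0 means above the surface; the gap is
#'   re-applied after every rotation).
#' @param dielectric relative dielectric constant (>= 1).
#' @param cutoff pair cutoff in Å; `Inf` disables truncation.
#' @param k_minima number of favourable orientations to select.
#' @param basin_separation minimal toroidal angular separation (degrees)
#'   between selected orientations.
#' @param coulomb_constant Coulomb constant in kcal Å mol^-1 e^-2.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(theta_step = 10, psi_step = 10, gap = 5,
                        dielectric = 1, cutoff = 30, k_minima = 2L,
                        basin_separation = 30,
                        coulomb_constant = COULOMB_K) {
  if (360 %% theta_step != 0 || 360 %% psi_step != 0)
    stop("angular steps must divide 360 evenly")
  if (gap <= 0) stop("gap must be > 0")
  if (dielectric < 1) stop("dielectric must be >= 1")
  if (!is.infinite(cutoff) && cutoff <= 0) stop("cutoff must be > 0 or Inf")
  structure(list(theta_step = theta_step, psi_step = psi_step, gap = gap,
                 dielectric = dielectric, cutoff = cutoff,
                 k_minima = as.integer(k_minima),
                 basin_separation = basin_separation,
                 coulomb_constant = coulomb_constant),
            class = "scan_config")
}

#' Rotation matrix for the two scan angles
#'
#' `R = R_y(psi) %*% R_x(theta)`: first the rotation about the laboratory
#' x-axis by theta, then about the y-axis by psi (both fixed lab axes).
#'
#' @param theta,psi angles in degrees.
#' @return 3 x 3 orthonormal rotation matrix (determinant +1).
#' @export
rotation_matrix <- function(theta, psi) {
  t <- theta * pi / 180
  p <- psi * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(t), -sin(t),
                 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(p), 0, sin(p),
                 0, 1, 0,
                 -sin(p), 0, cos(p)), 3, 3, byrow = TRUE)
  ry %*% rx
}

#' Rigidly rotate a model about its centre of geometry
#'
#' @param model a [molecular_model()].
#' @param theta,psi rotation angles in degrees (about the lab x- and y-axis
#'   respectively, applied in that order).
#' @return the rotated model (all pairwise distances preserved).
#' @export
rotate_model <- function(model, theta, psi) {
  x <- coords(model)
  cog <- colMeans(x)
  r <- rotation_matrix(theta, psi)
  coords(model) <- sweep(sweep(x, 2, cog) %*% t(r), 2, cog, "+")
  model
}

#' Place a model a fixed gap above a surface
#'
#' Centres the model laterally over the slab and translates it along z so
#' that the lowest atom sits exactly `gap` Å above the topmost SAM heavy
#' atom (`min(z) - top_z == gap`).  Applying the placement twice is a no-op.
#'
#' @param model a [molecular_model()].
#' @param surface a [build_sam_surface()] result.
#' @param gap vertical gap in Å.
#' @return the placed model.
#' @export
place_above <- function(model, surface, gap = 5) {
  x <- coords(model)
  dx <- surface$center_x - mean(x[, 1])
  dy <- surface$center_y - mean(x[, 2])
  dz <- surface$top_z + gap - min(x[, 3])
  width <- max(apply(x[, 1:2, drop = FALSE], 2,
                     function(v) diff(range(v))))
  if (width > min(surface$extent_x, surface$extent_y))
    warning("model footprint (", round(width, 1),
            " Angstrom) exceeds the slab extent; edge effects likely")
  coords(model) <- cbind(x[, 1] + dx, x[, 2] + dy, x[, 3] + dz)
  model
}

#' In vacuo Coulomb + Lennard-Jones interaction energy between two bodies
#'
#' Sum over cross pairs within the cutoff of
#' `ke * qi * qj / (eps_r * r) + eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)`
#' with `eps_ij = sqrt(eps_i eps_j)` and `Rmin_ij = rmin_half_i +
#' rmin_half_j`.  Intra-body pairs are never counted.  Overlapping
#' interacting atoms (zero distance) are an error.
#'
#' @param a a [molecular_model()].
#' @param b a [molecular_model()] or `surface_model`.
#' @param config a [scan_config()] supplying dielectric, cutoff and the
#'   Coulomb constant.
#' @return energy in kcal/mol.
#' @export
interaction_energy <- function(a, b, config = scan_config()) {
  aa <- a$atoms
  bb <- b$atoms
  pair_energy_cpp(coords(a), aa$charge, aa$lj_epsilon, aa$lj_rmin_half,
                  as.matrix(bb[, c("x", "y", "z")]), bb$charge,
                  bb$lj_epsilon, bb$lj_rmin_half,
                  config$coulomb_constant, config$dielectric,
                  if (is.infinite(config$cutoff)) -1 else config$cutoff)
}

#' Construct the (theta, psi) interaction-energy landscape
#'
#' For every grid point on the half-open grid \[0, 360) x \[0, 360) the
#' protein is rotated about its centre of geometry, re-placed `gap` Å above
#' the SAM, and the in vacuo interaction energy is evaluated.  The default
#' 10 degree step gives 36 x 36 = 1296 orientations.  Fully deterministic.
#'
#' @param protein a parameterized [molecular_model()].
#' @param surface a [build_sam_surface()] result.
#' @param config a [scan_config()].
#' @return an object of class `energy_landscape`: `theta_values`,
#'   `psi_values` (degrees), `energies` (matrix, rows theta, cols psi,
#'   kcal/mol), `config`, `provenance`.
#' @export
scan_orientations <- function(protein, surface, config = scan_config()) {
  theta_values <- seq(0, 360 - config$theta_step, by = config$theta_step)
  psi_values <- seq(0, 360 - config$psi_step, by = config$psi_step)
  bb <- surface$atoms
  xb <- as.matrix(bb[, c("x", "y", "z")])
  cut <- if (is.infinite(config$cutoff)) -1 else config$cutoff
  aa <- protein$atoms
  x0 <- coords(protein)
  cog <- colMeans(x0)
  xc <- sweep(x0, 2, cog)
  cx <- surface$center_x
  cy <- surface$center_y
  e <- matrix(NA_real_, length(theta_values), length(psi_values))
  for (i in seq_along(theta_values)) {
    for (j in seq_along(psi_values)) {
      r <- rotation_matrix(theta_values[i], psi_values[j])
      x <- xc %*% t(r)
      x[, 1] <- x[, 1] - mean(x[, 1]) + cx
      x[, 2] <- x[, 2] - mean(x[, 2]) + cy
      x[, 3] <- x[, 3] - min(x[, 3]) + surface$top_z + config$gap
      e[i, j] <- pair_energy_cpp(x, aa$charge, aa$lj_epsilon,
                                 aa$lj_rmin_half, xb, bb$charge,
                                 bb$lj_epsilon, bb$lj_rmin_half,
                                 config$coulomb_constant, config$dielectric,
                                 cut)
    }
  }
  energy_landscape(theta_values, psi_values, e, config,
                   provenance = list(protein = protein$name,
                                     n_protein_atoms = nrow(aa),
                                     n_surface_atoms = nrow(bb),
                                     surface_net_charge = surface$net_charge))
}

#' @rdname scan_orientations
#' @param theta_values,psi_values grid angles in degrees.
#' @param energies energy matrix (rows theta, cols psi).
#' @param provenance free-form list recording scan inputs.
#' @export
energy_landscape <- function(theta_values, psi_values, energies,
                             config = scan_config(), provenance = list()) {
  stopifnot(is.matrix(energies),
            nrow(energies) == length(theta_values),
            ncol(energies) == length(psi_values))
  if (!all(is.finite(energies))) stop("landscape energies must be finite")
  structure(list(theta_values = theta_values, psi_values = psi_values,
                 energies = energies, config = config,
                 provenance = provenance),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(paste0("<energy_landscape: %d x %d orientations, ",
                     "E in [%.2f, %.2f] kcal/mol>\n"),
              length(x$theta_values), length(x$psi_values),
              min(x$energies), max(x$energies)))
  invisible(x)
}

# wrap-aware angular distance in degrees
ang_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Select the energetically most favourable, mutually separated orientations
#'
#' Greedy selection: repeatedly take the lowest-energy grid point whose
#' toroidal angular distance `max(d_theta, d_psi)` (wrap-aware) from all
#' already-selected points is at least `separation`.  Deterministic; ties
#' are broken by ascending theta, then psi.  If the grid cannot honour the
#' separation, fewer than `k` poses are returned with a warning.
#'
#' @param landscape an [energy_landscape()].
#' @param k number of orientations to return.
#' @param separation minimal toroidal separation in degrees.
#' @return list of `pose` objects (theta, psi, rotation, energy).
#' @export
select_minima <- function(landscape, k = landscape$config$k_minima,
                          separation = landscape$config$basin_separation) {
  stopifnot(k >= 1)
  grid <- expand.grid(theta = landscape$theta_values,
                      psi = landscape$psi_values)
  grid$energy <- as.vector(landscape$energies)
  ord <- order(grid$energy, grid$theta, grid$psi)
  sel <- integer(0)
  for (idx in ord) {
    if (length(sel) >= k) break
    ok <- all(pmax(ang_dist(grid$theta[idx], grid$theta[sel]),
                   ang_dist(grid$psi[idx], grid$psi[sel])) >= separation)
    if (length(sel) == 0L || ok) sel <- c(sel, idx)
  }
  if (length(sel) < k)
    warning("grid too small to honour the separation; returning ",
            length(sel), " of ", k, " poses")
  lapply(sel, function(i)
    pose(theta = grid$theta[i], psi = grid$psi[i],
         energy = grid$energy[i]))
}

#' A single oriented pose
#'
#' @param theta,psi orientation angles in degrees.
#' @param energy interaction energy in kcal/mol.
#' @param translation optional placement translation (Å).
#' @param observables named list of derived observables.
#' @return an object of class `pose` carrying the orthonormal rotation
#'   matrix for (theta, psi).
#' @export
pose <- function(theta, psi, energy = NA_real_, translation = NULL,
                 observables = list()) {
  structure(list(theta = theta, psi = psi,
                 rotation = rotation_matrix(theta, psi),
                 translation = translation, energy = energy,
                 observables = observables),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose: theta %g, psi %g, E %.3f kcal/mol>\n",
              x$theta, x$psi, x$energy))
  invisible(x)
}

#' Interfacial electric field specification
#'
#' Describes a uniform field normal to the electrode used to re-rank
#' orientations by their dipole alignment.  Sign convention: positive
#' `field_z` points from the electrode into the solution (+z); the sign
#' actually applied is `sign(applied_potential - pzc)`, i.e. the field
#' flips direction when the applied potential crosses the potential of zero
#' charge (about -0.25 V for the SAM-coated Au electrode).
#'
#' @param field_z field magnitude in V/Å (its sign is overridden by the
#'   potential relative to the PZC).
#' @param pzc potential of zero charge in volts.
#' @param applied_potential applied electrode potential in volts.
#' @param weight dimensionless weight of the dipole-field term (>= 0).
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(field_z, pzc = -0.25, applied_potential = 0,
                       weight = 1) {
  if (weight < 0) stop("weight must be >= 0")
  structure(list(field_z = field_z, pzc = pzc,
                 applied_potential = applied_potential, weight = weight),
            class = "field_spec")
}

#' Dipole moment at every grid orientation
#'
#' Rotates the protein through the landscape's grid and records the dipole
#' vector at each orientation (placement does not change the dipole of a
#' rigid body about its own origin convention).
#'
#' @param protein a parameterized [molecular_model()].
#' @param landscape an [energy_landscape()] defining the grid.
#' @param origin origin convention passed to [dipole_moment()].
#' @return numeric array `[n_theta, n_psi, 3]` of dipole vectors in Debye.
#' @export
scan_dipoles <- function(protein, landscape, origin = "center_of_mass") {
  nt <- length(landscape$theta_values)
  np <- length(landscape$psi_values)
  out <- array(NA_real_, c(nt, np, 3))
  mu0 <- dipole_moment(protein, origin = origin)$vector
  for (i in seq_len(nt)) {
    for (j in seq_len(np)) {
      r <- rotation_matrix(landscape$theta_values[i],
                           landscape$psi_values[j])
      out[i, j, ] <- drop(r %*% mu0)
    }
  }
  out
}

#' Re-rank a landscape under an interfacial electric field
#'
#' Adds the dipole-field alignment energy to each grid point:
#' `S(theta, psi) = E(theta, psi) + weight * (-mu . E_field)`, with the
#' dipole in Debye and the field in V/Å converted to kcal/mol via
#' Debye -> e·Å (divide by 4.8032) and e·V -> kcal/mol (multiply by
#' 23.060548).  The field direction along z is `sign(applied_potential -
#' pzc)`: above the PZC the field points into the solution, below it the
#' field is reversed — which is what makes dipole-opposed orientations
#' swap rank across the PZC.
#'
#' @param landscape an [energy_landscape()].
#' @param dipoles `[n_theta, n_psi, 3]` array of per-orientation dipole
#'   vectors in Debye (see [scan_dipoles()]).
#' @param field a [field_spec()].
#' @return a new `energy_landscape` of scores (kcal/mol).
#' @export
field_rerank <- function(landscape, dipoles, field) {
  nt <- length(landscape$theta_values)
  np <- length(landscape$psi_values)
  if (is.null(dipoles) || !is.array(dipoles) ||
      !all(dim(dipoles) == c(nt, np, 3)) || anyNA(dipoles))
    stop("a dipole vector is required for every grid point")
  sgn <- sign(field$applied_potential - field$pzc)
  if (sgn == 0) sgn <- 1
  ez <- sgn * abs(field$field_z)
  term <- -dipoles[, , 3] * ez * DEBYE_VA_TO_KCAL
  energy_landscape(landscape$theta_values, landscape$psi_values,
                   landscape$energies + field$weight * term,
                   config = landscape$config,
                   provenance = c(landscape$provenance,
                                  list(field = unclass(field))))
}

#' Write / read a landscape as CSV
#'
#' Long format with columns `theta_deg, psi_deg, energy_kcal_mol`.
#'
#' @param landscape an [energy_landscape()].
#' @param path CSV file path.
#' @return `write_landscape_csv()` returns `path` invisibly;
#'   `read_landscape_csv()` returns an `energy_landscape` (with a default
#'   config and empty provenance).
#' @export
write_landscape_csv <- function(landscape, path) {
  grid <- expand.grid(theta_deg = landscape$theta_values,
                      psi_deg = landscape$psi_values)
  grid$energy_kcal_mol <- as.vector(landscape$energies)
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  d <- utils::read.csv(path)
  tv <- sort(unique(d$theta_deg))
  pv <- sort(unique(d$psi_deg))
  e <- matrix(NA_real_, length(tv), length(pv))
  e[cbind(match(d$theta_deg, tv), match(d$psi_deg, pv))] <- d$energy_kcal_mol
  step <- function(v) if (length(v) > 1) diff(v)[1] else 360
  energy_landscape(tv, pv, e,
                   config = scan_config(theta_step = step(tv),
                                        psi_step = step(pv)))
}

#' Write a landscape as JSON with provenance
#' @param landscape an [energy_landscape()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_landscape_json <- function(landscape, path) {
  jsonlite::write_json(
    list(theta_values = landscape$theta_values,
         psi_values = landscape$psi_values,
         energies = landscape$energies,
         config = unclass(landscape$config),
         provenance = landscape$provenance),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
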