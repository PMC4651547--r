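#' Macrodipole moment of a model
#'
#' `mu = 4.8032 * sum(q_i * (r_i - r_origin))` with charges in e and
#' coordinates in Å, giving Debye.  For a neutral body the result is
#' origin-independent; for a charged body it is not, so the record stores
#' the origin convention and the net charge.
#'
#' @param model a parameterized [molecular_model()].
#' @param origin `"center_of_mass"` (default; unit masses when elements are
#'   unknown), `"center_of_geometry"`, or a numeric length-3 point in Å.
#' @return an object of class `dipole_record`: `vector` (Debye),
#'   `magnitude`, `angle_to_normal` (degrees to +z, `NA` for a vanishing
#'   dipole), `origin`, `net_charge`.
#' @export
dipole_moment <- function(model, origin = "center_of_mass") {
  x <- coords(model)
  q <- model$atoms$charge
  o <- if (is.numeric(origin)) {
    stopifnot(length(origin) == 3)
    origin
  } else switch(match.arg(origin, c("center_of_mass", "center_of_geometry")),
                center_of_mass = center_of_mass(model),
                center_of_geometry = center_of_geometry(model))
  mu <- EA_TO_DEBYE * unname(drop(q %*% sweep(x, 2, o)))
  mag <- sqrt(sum(mu^2))
  ang <- if (mag > 0) acos(pmin(1, pmax(-1, mu[3] / mag))) * 180 / pi
         else NA_real_
  structure(list(vector = mu, magnitude = mag, angle_to_normal = ang,
                 origin = if (is.numeric(origin)) "custom" else origin,
                 net_charge = sum(q)),
            class = "dipole_record")
}

#' @export
print.dipole_record <- function(x, ...) {
  cat(sprintf("<dipole: %.2f Debye, %.1f deg to surface normal (%s)>\n",
              x$magnitude, x$angle_to_normal, x$origin))
  invisible(x)
}

#' Directional statistics of a dipole pseudo-trajectory
#'
#' Computes the per-frame dipole, the mean direction (normalised vector
#' mean of the unit dipoles), the angular spread — the circular standard
#' deviation `sqrt(-2 log(Rbar))` in degrees, where `Rbar` is the mean
#' resultant length — and the mean/SD of the dipole magnitude.  A small
#' spread means the dipole direction is nearly static (as for an enzyme
#' pinned on a surface); a large one means it fluctuates freely.
#'
#' @param frames list of at least two [molecular_model()]s with a common
#'   atom count (e.g. MODEL blocks of a multi-model PDB read with
#'   `read_structure(multi = TRUE)`).
#' @param origin origin convention, see [dipole_moment()].
#' @return an object of class `trajectory_stats`: `n_frames`,
#'   `mean_direction` (unit 3-vector), `angular_spread` (degrees),
#'   `magnitude_mean`, `magnitude_sd` (Debye).
#' @export
trajectory_dipole_stats <- function(frames, origin = "center_of_mass") {
  stopifnot(length(frames) >= 2)
  counts <- vapply(frames, n_atoms, integer(1))
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom counts across frames")
  mu <- t(vapply(frames, function(f) dipole_moment(f, origin)$vector,
                 numeric(3)))
  mags <- sqrt(rowSums(mu^2))
  if (any(mags == 0)) stop("zero dipole in at least one frame")
  units <- mu / mags
  mean_vec <- colMeans(units)
  rbar <- sqrt(sum(mean_vec^2))
  structure(list(n_frames = length(frames),
                 mean_direction = mean_vec / rbar,
                 angular_spread = sqrt(max(0, -2 * log(rbar))) * 180 / pi,
                 magnitude_mean = mean(mags),
                 magnitude_sd = stats::sd(mags)),
            class = "trajectory_stats")
}

#' @export
print.trajectory_stats <- function(x, ...) {
  cat(sprintf(paste0("<trajectory_stats: %d frames, spread %.2f deg, ",
                     "|mu| = %.2f +/- %.2f Debye>\n"),
              x$n_frames, x$angular_spread, x$magnitude_mean,
              x$magnitude_sd))
  invisible(x)
}

#' Perpendicular distance from a selection to a surface reference plane
#'
#' The z distance from the centroid of the selected atoms (e.g. the Ni of
#' the \[NiFe\] site, or the distal FeS cluster) to the chosen reference
#' plane: `sam_top` (topmost SAM heavy atom, default) or `au_top` (the Au
#' layer).
#'
#' @param model a [molecular_model()] with the named selection.
#' @param selection selection label.
#' @param surface a [build_sam_surface()] result.
#' @param reference `"sam_top"` or `"au_top"`.
#' @return signed distance in Å (positive above the plane).
#' @export
surface_distance <- function(model, selection, surface,
                             reference = c("sam_top", "au_top")) {
  reference <- match.arg(reference)
  idx <- get_selection(model, selection)
  ref_z <- switch(reference,
                  sam_top = surface$top_z,
                  au_top = max(surface$atoms$z[has_tag(surface$atoms$tags,
                                                       "gold")]))
  mean(model$atoms$z[idx]) - ref_z
}

#' Optimal-superposition (Kabsch) RMSD
#'
#' Least-squares rigid superposition (rotation + translation, reflection
#' disallowed) of the mobile onto the reference selection, by the Kabsch
#' SVD construction at full floating-point precision.  Used as the
#' structural-integrity check: the backbone of an adsorbed pose superposes
#' on the crystal structure within a few Å if the fold is intact.
#'
#' @param reference,mobile [molecular_model()]s.
#' @param selection optional selection label present in both models; by
#'   default all atoms are used.  Selected atom counts must match.
#' @return RMSD in Å.
#' @export
kabsch_rmsd <- function(reference, mobile, selection = NULL) {
  xa <- coords(reference)
  xb <- coords(mobile)
  if (!is.null(selection)) {
    xa <- xa[get_selection(reference, selection), , drop = FALSE]
    xb <- xb[get_selection(mobile, selection), , drop = FALSE]
  }
  if (nrow(xa) != nrow(xb))
    stop("selected atom counts differ: ", nrow(xa), " vs ", nrow(xb))
  pa <- sweep(xa, 2, colMeans(xa))
  pb <- sweep(xb, 2, colMeans(xb))
  s <- svd(crossprod(pb, pa))
  d <- sign(det(s$u %*% t(s$v)))     # guard against improper rotations
  r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((pa - pb %*% r)^2)))
}

#' Monolayer coverage of hexagonally close-packed disks
#'
#' Treats each adsorbed molecule as a disk of the given diameter (e.g. the
#' ~9 nm lateral periodicity seen by AFM) packed hexagonally:
#' `Gamma = 1 / (N_A * (sqrt(3)/2) * d^2)` in mol per area, reported in
#' pmol/cm².
#'
#' @param diameter molecular footprint diameter in nm.
#' @param molecular_weight optional molar mass in g/mol, to also report the
#'   mass coverage.
#' @return an object of class `coverage_estimate`: `molar_coverage`
#'   (pmol/cm²), `mass_coverage` (ng/cm², `NA` without a molecular weight),
#'   `method`, `inputs`.
#' @export
coverage_hex_packing <- function(diameter, molecular_weight = NA) {
  stopifnot(diameter > 0)
  area_cm2 <- (sqrt(3) / 2) * (diameter * 1e-7)^2
  molar <- 1 / (AVOGADRO * area_cm2)          # mol/cm^2
  mass <- molar * molecular_weight * 1e9      # ng/cm^2
  structure(list(molar_coverage = molar * 1e12, mass_coverage = mass,
                 method = "hex_packing",
                 inputs = list(diameter_nm = diameter,
                               molecular_weight = molecular_weight)),
            class = "coverage_estimate")
}

#' Adsorbed-protein coverage from ellipsometry (de Feijter)
#'
#' `Gamma_mass = thickness * (n_film - n_ambient) / (dn/dc)` converts an
#' optical film thickness and the refractive-index increment of the protein
#' into adsorbed mass per area; division by the molar mass gives the molar
#' coverage.
#'
#' @param thickness film thickness in nm (>= 0).
#' @param n_film,n_ambient refractive indices of the film and the ambient
#'   medium (`n_film >= n_ambient` for a physical film).
#' @param dn_dc refractive-index increment in cm³/g (> 0; ~0.18 for
#'   proteins).
#' @param molecular_weight molar mass in g/mol.
#' @return a `coverage_estimate` (see [coverage_hex_packing()]).
#' @export
coverage_de_feijter <- function(thickness, n_film, n_ambient, dn_dc,
                                molecular_weight) {
  stopifnot(dn_dc > 0, thickness >= 0)
  if (n_film < n_ambient)
    stop("n_film < n_ambient: nonphysical film")
  mass_g_cm2 <- (thickness * 1e-7) * (n_film - n_ambient) / dn_dc
  structure(list(molar_coverage = mass_g_cm2 / molecular_weight * 1e12,
                 mass_coverage = mass_g_cm2 * 1e9,
                 method = "de_feijter",
                 inputs = list(thickness_nm = thickness, n_film = n_film,
                               n_ambient = n_ambient, dn_dc = dn_dc,
                               molecular_weight = molecular_weight)),
            class = "coverage_estimate")
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("<coverage (%s): %.3g pmol/cm^2%s>\n", x$method,
              x$molar_coverage,
              if (is.na(x$mass_coverage)) ""
              else sprintf(", %.3g ng/cm^2", x$mass_coverage)))
  invisible(x)
}
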