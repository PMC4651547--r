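#' Specification of the SAM-on-Au slab
#'
#' Defaults describe a 6-amino-1-hexanethiol monolayer chemisorbed on
#' Au(111): thiols on the canonical (sqrt(3) x sqrt(3))R30 overlayer with
#' 4.995 Å spacing, each chain an untilted all-trans pseudo-atom stack
#' (S anchor, six carbons, amino headgroup, 1.25 Å z-increments), and 8% of
#' the amino headgroups protonated (+1 e each) as expected near pH 7 for a
#' surface pKa of about 6.  The default 25 x 28 lattice gives a slab of
#' 124.9 Å x 121.1 Å (>= 120 Å in both directions, so a protein footprint
#' never overhangs) whose 700 chains carry the 8% protonation exactly
#' (56 chains).
#'
#' @param nx,ny lattice repeats (>= 1).
#' @param thiol_spacing thiol-thiol spacing in Å.
#' @param protonation_fraction fraction of amino headgroups protonated, in
#'   \[0, 1\].
#' @param headgroup_charge_protonated charge of a protonated headgroup in e.
#' @param seed seed for the placement of protonated chains.
#' @param gold_layers number of Au pseudo-layers beneath the anchors
#'   (Lennard-Jones only, zero charge).
#' @param chain data frame describing one chain bottom-up: columns
#'   `atom_name`, `element`, `z_offset` (Å above the S anchor), `lj_epsilon`,
#'   `lj_rmin_half`.  The last row is the headgroup that carries the
#'   protonation charge.
#' @return an object of class `surface_spec`.
#' @export
surface_spec <- function(nx = 25L, ny = 28L, thiol_spacing = 4.995,
                         protonation_fraction = 0.08,
                         headgroup_charge_protonated = 1,
                         seed = 1L, gold_layers = 1L,
                         chain = default_sam_chain()) {
  if (thiol_spacing <= 0) stop("thiol_spacing must be > 0")
  if (protonation_fraction < 0 || protonation_fraction > 1)
    stop("protonation_fraction must be in [0, 1]")
  if (nx < 1 || ny < 1) stop("nx and ny must be >= 1")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 thiol_spacing = thiol_spacing,
                 protonation_fraction = protonation_fraction,
                 headgroup_charge_protonated = headgroup_charge_protonated,
                 seed = as.integer(seed),
                 gold_layers = as.integer(gold_layers),
                 chain = chain),
            class = "surface_spec")
}

#' @rdname surface_spec
#' @export
default_sam_chain <- function() {
  data.frame(
    atom_name = c("S", paste0("C", 1:6), "N"),
    element = c("S", rep("C", 6), "N"),
    z_offset = seq(0, by = 1.25, length.out = 8),
    lj_epsilon = c(0.45, rep(0.07, 6), 0.20),
    lj_rmin_half = c(2.0, rep(2.0, 6), 1.85),
    stringsAsFactors = FALSE)
}

#' Henderson-Hasselbalch protonated fraction
#'
#' Fraction of protonated (-NH3+) amino headgroups for a weak base of the
#' given surface pKa at the given pH: `1 / (1 + 10^(pH - pKa))`.  At pH 7
#' with pKa near 6 this is about 0.08-0.09, the partial protonation assumed
#' for the amino-hexanethiol SAM.
#'
#' @param pH solution pH.
#' @param pKa acid dissociation constant of the surface-attached headgroup.
#' @return fraction in \[0, 1\].
#' @export
protonated_fraction <- function(pH, pKa) {
  1 / (1 + 10^(pH - pKa))
}

#' Choose which SAM chains are protonated
#'
#' Draws `round(fraction * n_chains)` distinct chain indices uniformly
#' without replacement from a seeded generator, so the same
#' `(n_chains, fraction, seed)` always yields the same set.  The caller's
#' RNG state is left untouched.
#'
#' @param n_chains number of chains (>= 1).
#' @param fraction protonated fraction in \[0, 1\].
#' @param seed integer seed.
#' @return sorted integer vector of protonated chain indices.
#' @export
assign_protonation <- function(n_chains, fraction, seed = 1L) {
  stopifnot(n_chains >= 1, fraction >= 0, fraction <= 1)
  k <- round(fraction * n_chains)
  if (k == 0) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sort(sample.int(n_chains, k))
}

#' Build the SAM-coated Au slab
#'
#' Thiol anchors sit on a hexagonal lattice with the spacing of the spec;
#' each chain is an all-trans vertical pseudo-atom stack topped by the amino
#' headgroup.  Protonated chains (chosen by [assign_protonation()]) carry
#' `headgroup_charge_protonated` on the headgroup atom; all other SAM atoms
#' are neutral.  A single hexagonal Au pseudo-layer (nearest-neighbour
#' 2.884 Å, Lennard-Jones only, zero charge — polarization/image charges are
#' deliberately excluded from this in vacuo screen) lies beneath the
#' anchors, which sit 2.4 Å above it.
#'
#' @param spec a [surface_spec()].
#' @return an object of class `surface_model`: list with `atoms` (as in
#'   [molecular_model()]), `top_z` (height of the highest SAM heavy atom),
#'   `normal` (+z), `protonated_indices` (chain indices), `net_charge`,
#'   `extent_x`, `extent_y`, and the originating `spec`.
#' @export
build_sam_surface <- function(spec = surface_spec()) {
  stopifnot(inherits(spec, "surface_spec"))
  s <- spec$thiol_spacing
  n_chains <- spec$nx * spec$ny
  extent_x <- spec$nx * s
  extent_y <- spec$ny * s * sqrt(3) / 2

  ij <- expand.grid(i = seq_len(spec$nx) - 1L, j = seq_len(spec$ny) - 1L)
  anchor_x <- ij$i * s + (ij$j %% 2) * s / 2
  anchor_y <- ij$j * s * sqrt(3) / 2

  prot <- assign_protonation(n_chains, spec$protonation_fraction, spec$seed)

  chain <- spec$chain
  n_per <- nrow(chain)
  head_row <- n_per
  s_base_z <- 2.4  # S anchor height above the Au plane
  idx_chain <- rep(seq_len(n_chains), each = n_per)
  idx_atom <- rep(seq_len(n_per), times = n_chains)
  charge <- ifelse(idx_atom == head_row & idx_chain %in% prot,
                   spec$headgroup_charge_protonated, 0)
  sam <- data.frame(
    atom_name = chain$atom_name[idx_atom],
    element = chain$element[idx_atom],
    residue_name = "SAM",
    residue_number = idx_chain,
    chain_id = "S",
    x = anchor_x[idx_chain],
    y = anchor_y[idx_chain],
    z = s_base_z + chain$z_offset[idx_atom],
    charge = charge,
    lj_epsilon = chain$lj_epsilon[idx_atom],
    lj_rmin_half = chain$lj_rmin_half[idx_atom],
    tags = "sam", stringsAsFactors = FALSE)

  au <- NULL
  if (spec$gold_layers >= 1) {
    a_au <- 2.884
    gx <- seq(0, extent_x, by = a_au)
    gy <- seq(0, extent_y, by = a_au * sqrt(3) / 2)
    gg <- expand.grid(i = seq_along(gx) - 1L, j = seq_along(gy) - 1L)
    au <- data.frame(
      atom_name = "AU", element = "AU", residue_name = "AU",
      residue_number = seq_len(nrow(gg)), chain_id = "Z",
      x = gx[gg$i + 1L] + (gg$j %% 2) * a_au / 2,
      y = gy[gg$j + 1L],
      z = 0,
      charge = 0, lj_epsilon = 0.39, lj_rmin_half = 1.48,
      tags = "gold", stringsAsFactors = FALSE)
  }

  atoms <- rbind(sam, au)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 top_z = max(sam$z),
                 # lateral centroid of the thiol anchors; placement centres
                 # the protein here, not at extent/2, so finite-slab edge
                 # asymmetry does not bias the scan
                 center_x = mean(anchor_x), center_y = mean(anchor_y),
                 normal = c(0, 0, 1),
                 protonated_indices = prot,
                 net_charge = length(prot) * spec$headgroup_charge_protonated,
                 extent_x = extent_x, extent_y = extent_y,
                 spec = spec),
            class = "surface_model")
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf(paste0("<surface_model: %d chains (%d protonated, %.1f%%), ",
                     "%d atoms, net %+.1f e, %.1f x %.1f Angstrom>\n"),
              x$spec$nx * x$spec$ny, length(x$protonated_indices),
              100 * length(x$protonated_indices) / (x$spec$nx * x$spec$ny),
              nrow(x$atoms), x$net_charge, x$extent_x, x$extent_y))
  invisible(x)
}

#' Export a surface as a molecular model (e.g. for PDB visualisation)
#' @param surface a `surface_model`.
#' @return a [molecular_model()] with the same atoms.
#' @export
surface_as_model <- function(surface) {
  molecular_model(surface$atoms, name = "sam_surface")
}
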