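# Independent oracles and small fixture builders used across the suite.

# Brute-force O(N^2) Coulomb + Lennard-Jones cross energy, vectorized base R.
# Deliberately independent of the package's compiled kernel.
oracle_energy <- function(a, b, ke = 332.0636, dielectric = 1,
                          cutoff = Inf) {
  xa <- coords(a); xb <- as.matrix(b$atoms[, c("x", "y", "z")])
  qa <- a$atoms$charge; qb <- b$atoms$charge
  ea <- a$atoms$lj_epsilon; eb <- b$atoms$lj_epsilon
  ra <- a$atoms$lj_rmin_half; rb <- b$atoms$lj_rmin_half
  r <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  keep <- r <= cutoff
  qq <- outer(qa, qb)
  eps <- sqrt(outer(ea, eb))
  rmin <- outer(ra, rb, "+")
  sr6 <- (rmin / r)^6
  e <- ke * qq / (dielectric * r) + eps * (sr6^2 - 2 * sr6)
  sum(e[keep])
}

# Random parameterized rigid body for kernel / rigidity checks.
random_body <- function(n, seed, spread = 10, charged = TRUE) {
  set.seed(seed)
  molecular_model(data.frame(
    x = runif(n, -spread, spread),
    y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    charge = if (charged) runif(n, -0.5, 0.5) else 0,
    lj_epsilon = runif(n, 0, 0.2),
    lj_rmin_half = runif(n, 1, 2)),
    name = sprintf("random%d", seed))
}

# Hand-written three-atom PDB fragment (wwPDB v3.3 columns).
write_tiny_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104  13.207   2.100  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560  13.329   2.384  1.00  0.00           C",
    "HETATM    3 FE   HEM A   2       1.000  -2.500   3.750  1.00  0.00          FE",
    "END"), path)
  path
}

# Toroidal Chebyshev distance in degrees.
tor_cheb <- function(t1, p1, t2, p2) {
  d <- function(a, b) {
    x <- abs(a - b) %% 360
    pmin(x, 360 - x)
  }
  pmax(d(t1, t2), d(p1, p2))
}

# Heavy-atom Lys residue (no hydrogens), for parameterization checks.
lys_residue <- function() {
  molecular_model(data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C", "N"),
    residue_name = "LYS", residue_number = 1L, chain_id = "A",
    x = seq(0, 8), y = 0, z = 0,
    charge = 0, lj_epsilon = 0, lj_rmin_half = 0, tags = "",
    stringsAsFactors = FALSE), name = "lys")
}
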