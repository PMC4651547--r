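#include <Rcpp.h>
using namespace Rcpp;

// In vacuo Coulomb + Lennard-Jones cross-interaction energy between two
// rigid bodies.  Plain double loop over cross pairs (intra-body pairs are
// never formed); cutoff <= 0 means no truncation.  Combination rules:
// eps_ij = sqrt(eps_i * eps_j), Rmin_ij = rmin_half_i + rmin_half_j.
// Units: coordinates Angstrom, charges e, energies kcal/mol.
// [[Rcpp::export]]
double pair_energy_cpp(NumericMatrix xa, NumericVector qa,
                       NumericVector ea, NumericVector ra,
                       NumericMatrix xb, NumericVector qb,
                       NumericVector eb, NumericVector rb,
                       double ke, double dielectric, double cutoff) {
  const int na = xa.nrow(), nb = xb.nrow();
  const double cut2 = cutoff > 0 ? cutoff * cutoff : R_PosInf;
  double e = 0.0;
  for (int i = 0; i < na; ++i) {
    const double xi = xa(i, 0), yi = xa(i, 1), zi = xa(i, 2);
    const double qi = qa[i], ei = ea[i], ri = ra[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - xb(j, 0);
      const double dy = yi - xb(j, 1);
      const double dz = zi - xb(j, 2);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > cut2) continue;
      if (r2 == 0.0) {
        if (qi * qb[j] != 0.0 || ei * eb[j] != 0.0)
          stop("overlapping interacting atoms at zero distance");
        continue;
      }
      const double r = std::sqrt(r2);
      if (qi != 0.0 && qb[j] != 0.0)
        e += ke * qi * qb[j] / (dielectric * r);
      const double epsij = std::sqrt(ei * eb[j]);
      if (epsij > 0.0) {
        const double sr = (ri + rb[j]) / r;
        const double sr2 = sr * sr;
        const double sr6 = sr2 * sr2 * sr2;
        e += epsij * (sr6 * sr6 - 2.0 * sr6);
      }
    }
  }
  return e;
}
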