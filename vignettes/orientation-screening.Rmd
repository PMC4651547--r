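---
title: "Rigid-body orientation screening of a charged protein on a SAM-coated gold electrode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rigid-body orientation screening on SAM-coated electrodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samscan)
```

## The problem

When a redox enzyme such as an O$_2$-tolerant membrane-bound [NiFe]
hydrogenase adsorbs on an amino-alkanethiol SAM covering a gold electrode,
its orientation decides everything that matters electrochemically: whether
the distal FeS cluster — the natural exit point of the electron relay —
ends up close enough to the electrode for direct electron transfer, or
points into solution so that only a diffusing mediator can shuttle
electrons.  `samscan` implements the desk-scale half of that analysis: a
coarse rigid-body screen of protein orientations above a model SAM slab,
scored by in vacuo Coulomb + Lennard-Jones interaction energies, followed
by per-orientation observables (macrodipole, dipole angle to the surface
normal, cofactor–surface distances, superposition RMSD) and a dipole–field
re-ranking term that rationalises potential-induced re-orientation around
the potential of zero charge (PZC).

The screen is deliberately coarse.  It is the stage that *precedes*
explicit-solvent molecular dynamics in the full workflow: its job is to
find a small number of plausible starting orientations, not to predict
binding free energies.  Everything downstream of the screen (solvation,
relaxation, the MD-refined distances) is out of scope here.

## The model

### Protein

A structure read from PDB or PQR (`read_structure()`) is treated as a
rigid body.  Charges come from a packaged residue-level table
(`default_forcefield()`): heavy atoms only, each implicit hydrogen's
charge folded into its parent heavy atom, and per-residue sums equal to
the formal charge at pH 7 — Asp/Glu $-1$ (split over the carboxylate
oxygens), Lys/Arg $+1$ (on the terminal nitrogen(s)), His neutral, free
chain termini $\pm 1$ (toggleable).  This is a deterministic,
dependency-free approximation of an all-atom force-field charge set; it
reproduces formal-charge electrostatics (monopole and the dominant part of
the macrodipole) but not sub-residue charge detail.  Cofactors ([NiFe]
site, FeS clusters) arrive as HETATM groups; no published charge set
exists for them at this level, so they default to zero with a warning and
can be supplied per atom via `parameterize(hetero_charges = ...)`.

A C-terminal stretch unresolved in a crystal structure (for the MBH small
subunit: the hydrophobic tail carrying the Strep-tag II) can be appended
as a C$\alpha$-only trace on an ideal $\alpha$-helix
(`append_cterm_helix()`: radius 2.3 Å, rise 1.5 Å/residue, twist
100°/residue, axis continuing the local chain direction).  Appended
residues are parameterized like any others, so charged tag residues do
carry their formal charges in the screen.

### Surface

`build_sam_surface()` places 6-amino-1-hexanethiol chains on the canonical
$(\sqrt3\times\sqrt3)R30°$ overlayer of Au(111) (thiol spacing 4.995 Å,
Au nearest-neighbour 2.884 Å).  Each chain is an untilted all-trans
pseudo-atom stack (S anchor 2.4 Å above the Au plane, six carbons and the
amino headgroup at 1.25 Å z-increments); chain tilt and gauche defects
belong to the MD stage, not to a rigid screen.  A fraction of headgroups
— 8% by default, consistent with a Henderson–Hasselbalch fraction
$1/(1+10^{\mathrm{pH}-\mathrm{p}K_a})$ at pH 7 for a surface p$K_a$ of
about 6 — carries $+1\,e$; the protonated chains are chosen by seeded
uniform sampling (`assign_protonation()`, default seed 1) because their
physical placement is unknown and determinism is required.  The single Au
pseudo-layer interacts only through Lennard-Jones terms: the screen is in
vacuo and neglects polarization, so image charges are deliberately absent.

The default lattice is $25 \times 28$ sites.  Two constraints picked this
value: the slab must be at least 120 Å in both directions so a protein
footprint never overhangs (hexagonal rows are compressed by $\sin 60°$,
which rules out a square repeat count), and the chain count must carry the
8% protonation exactly — $0.08 \times 700 = 56$ chains.  Placement centres
the protein over the *centroid of the thiol anchors*, not over the
geometric half-extent: on a finite slab with offset hexagonal rows the two
differ by half a row spacing, and centring on the half-extent visibly
biases the scan toward tilted orientations.

### Energy and scan

The interaction energy between protein atoms $i$ and surface atoms $j$ is

$$E = \sum_{ij}\left[\frac{k_e\,q_i q_j}{\varepsilon_r\,r_{ij}}
 + \epsilon_{ij}\!\left(\left(\tfrac{R_{ij}}{r_{ij}}\right)^{12}
 - 2\left(\tfrac{R_{ij}}{r_{ij}}\right)^{6}\right)\right],$$

with $k_e = 332.0636$ kcal Å mol$^{-1}$ e$^{-2}$,
$\epsilon_{ij}=\sqrt{\epsilon_i\epsilon_j}$,
$R_{ij}=R^{min}_i/2+R^{min}_j/2$, $\varepsilon_r = 1$ (in vacuo; exposed
for sensitivity runs) and a plain 30 Å cutoff (no switching function;
`cutoff = Inf` disables truncation for oracle comparisons).  The kernel is
a compiled double loop over cross pairs; at desk scale
($\lesssim 10^3 \times 10^4$ atoms $\times$ 1296 orientations) no spatial
binning is needed, and the plain loop is trivially identical to the
brute-force contract the tests enforce.

Orientations are two angles: $R = R_y(\psi)\,R_x(\theta)$ about fixed
laboratory axes, applied about the protein's centre of geometry, on the
half-open grid $[0°,360°)\times[0°,360°)$ in 10° steps (36 × 36 = 1296
orientations).  After every rotation the body is re-placed so its lowest
atom sits exactly 5 Å above the topmost SAM heavy atom — the gap reference
is a convention (lowest atom to SAM top plane) chosen for reproducibility.
`select_minima()` then greedily picks the lowest-energy grid points that
are mutually separated by at least 30° in toroidal Chebyshev distance
$\max(\Delta\theta,\Delta\psi)$, ties broken by ascending $\theta$ then
$\psi$; the default returns two candidate orientations.

### Dipole, field re-ranking and observables

The macrodipole is $\vec\mu = 4.8032\sum_i q_i(\vec r_i - \vec r_0)$ Debye
(charges in e, coordinates in Å), with the centre of mass as the default
origin; for a charged protein the dipole is origin-dependent, so the
record stores the convention and the net charge.  The dipole–field score

$$S(\theta,\psi) = E(\theta,\psi) + w\,(-\vec\mu\cdot\vec E)$$

adds a uniform interfacial field along the surface normal whose sign is
$\mathrm{sign}(V_{applied} - V_{pzc})$ with $V_{pzc} = -0.25$ V by
default: crossing the PZC flips the field and therefore which of two
dipole-opposed orientations ranks lower — the proposed mechanism for
re-orientation during pre-activation at potentials below the PZC.  The
conversion runs Debye $\to$ e·Å ($\div\,4.8032$) then e·V $\to$ kcal/mol
($\times\,23.060548$); the field magnitude and the weight $w$ are user
inputs, never defaulted to a claimed physical value, because the screen
can only argue this term qualitatively.

Directional statistics of dipole pseudo-trajectories use the circular
standard deviation $\sqrt{-2\ln\bar R}$ (degrees), where $\bar R$ is the
mean resultant length of the per-frame unit dipoles.  Cofactor–surface
distances are perpendicular distances from a tagged selection's centroid
to either the SAM top plane or the Au plane (both offered, since "distance
to the electrode" is ambiguous between the two).  Superposition RMSD is
the Kabsch SVD construction with the determinant correction that forbids
reflections.  Coverage estimators: hexagonal close packing of disks,
$\Gamma = 1/(N_A\,\tfrac{\sqrt3}{2}d^2)$, and the de Feijter relation
$\Gamma = t\,(n_f - n_a)/(dn/dc)$.

## Synthetic generators and what passing tests show

Because the screen's real input (a crystal structure) is an external
download, every stage is validated against generators with closed-form
ground truth (all pure functions of their seed):

* `make_dumbbell()` — analytic dipole $4.8032\,q\,d$ Debye, zero net
  charge.
* `make_patchy_sphere()` — a Fibonacci-lattice shell with a charged polar
  cap; over an oppositely charged slab the known optimum turns the cap to
  the surface.  On the discrete 8%-protonated slab the cap-down cone of
  orientations is nearly degenerate (the exact grid argmin moves by one
  10° step depending on where the discrete charges happen to sit), so
  tests assert cap-facing orientation plus oracle-equal energies there,
  and exact $(0°,180°)/(180°,0°)$ recovery on a laterally homogeneous slab
  of the same net charge, where the idealised symmetry actually holds.
* `make_two_basin_landscape()` — two wrapped Gaussian wells (depths 10 and
  8 kcal/mol) plus seeded noise.  The default width is 15°: it must not
  exceed half the 30° selection separation, otherwise the deeper well's
  flank just outside the exclusion zone competes with the shallower
  planted centre and the configuration is unidentifiable *in principle*.
  "Recovery" means landing within one grid step of a planted centre:
  under noise the argmin of the noisy surface genuinely moves one step
  with non-negligible probability, so exact-grid-point recovery is not an
  achievable target for any method.
* `make_vmf_dipole_trajectory()` — von Mises–Fisher directional noise
  (standard inversion sampler) with fixed dipole magnitude; the
  independent oracle is the closed-form spread
  $\sqrt{-2\ln(\coth\kappa - 1/\kappa)}$ and Banerjee's concentration
  estimator, neither of which shares code with the sampler.

What passing tests do *not* show: that the screen's energies are accurate
for a real protein (the charge model is residue-level and in vacuo), that
the selected orientations survive solvation and relaxation, or that the
toy bodies resemble protein shapes.  The generators validate the
*machinery* — kernel, grid, placement, selection, statistics — not the
chemistry.

## Worked example

```{r example, eval = FALSE}
protein <- make_patchy_sphere()                          # -1 e charge patch
surface <- build_sam_surface(surface_spec(nx = 10, ny = 10))  # +8 e slab
landscape <- scan_orientations(protein, surface, scan_config())
poses <- select_minima(landscape)                        # two orientations
vapply(poses, function(p) c(theta = p$theta, psi = p$psi,
                            E = p$energy), numeric(3))
```

The same computation, narrated and written to `results/`, lives in the
numbered scripts under `analysis/`; `run_pipeline()` executes the full
chain (structure → parameterize → surface → scan → minima → observables →
report) from a single YAML config with one seed and bit-identical reruns.

## Numerical choices and problem sizes

* Constants are centralised: $k_e = 332.0636$, 1 e·Å = 4.8032 D,
  1 e·V = 23.060548 kcal/mol, $N_A = 6.02214076\times10^{23}$.
* The kernel errors on coincident interacting atoms rather than returning
  an infinity.
* Tests and the bundled analyses use a 200-atom toy body over a 10 × 10
  slab (about 1100 atoms) for full 36 × 36 scans, and the 25 × 28 default
  slab where the slab geometry itself is under test; these sizes keep a
  full validation run around a minute on one CPU while exercising every
  code path at the default grid resolution.
* Landscape determinism is exact (no RNG in the scan); generator seeds
  save and restore the caller's RNG state.

## Limitations

* In vacuo, $\varepsilon_r = 1$, no solvent screening, no gold
  polarization/image charges: energies are screening scores, not binding
  energies.
* Residue-level charges cannot reproduce an all-atom dipole exactly; a
  published value of ~680 D for the reduced HoxGK heterodimer is the kind
  of quantity this charge model approximates, with sensitivity to the
  termini and cofactor-charge choices documented above.
* The SAM is rigid and untilted; the protein is rigid; the C-terminal
  extension is a C$\alpha$ trace.
* No periodic images: the slab is a finite patch, with lateral-shift
  energy variation below 1% of the interaction energy on the idealised
  homogeneous slab (and dominated by discrete-protonation granularity on
  the random one).
* Crystal-structure inputs (e.g. PDB entry 3RGW) are not bundled and must
  be supplied by the user.
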