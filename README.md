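# samscan

Rigid-body orientation screening of charged proteins on SAM-coated gold
electrodes, in R.

Bioelectrochemists immobilising redox enzymes — the motivating system is
an O₂-tolerant membrane-bound [NiFe] hydrogenase on a gold electrode
coated with a 6-amino-1-hexanethiol self-assembled monolayer (SAM) — need
to know how the protein sits on the surface: orientation decides whether
the distal FeS cluster is close enough to the electrode for direct
electron transfer or whether catalysis needs a diffusing mediator.
`samscan` implements the desk-scale screen that answers this before any
molecular dynamics is run.

## What it computes

* **SAM-on-Au(111) slab** with a configurable protonated-amino fraction
  (default 8%, the Henderson–Hasselbalch fraction
  1/(1+10^(pH−pKa)) near pH 7 for a surface pKa ≈ 6), thiols on the
  (√3×√3)R30° overlayer at 4.995 Å spacing.
* **Orientation energy landscape**: the protein, parameterized from a
  packaged residue-level charge table, is rotated through
  R_y(ψ)·R_x(θ) in 10° steps over [0°,360°)², placed 5 Å above the SAM
  at every step, and scored with in vacuo Coulomb + Lennard-Jones
  energies

      E = Σᵢⱼ [ kₑ qᵢqⱼ/(εᵣ rᵢⱼ) + εᵢⱼ((Rᵢⱼ/rᵢⱼ)¹² − 2(Rᵢⱼ/rᵢⱼ)⁶) ]

  (kₑ = 332.0636 kcal·Å·mol⁻¹·e⁻², compiled kernel, verified against a
  brute-force double loop).
* **Favourable orientations**: greedy selection of the k lowest,
  mutually separated grid minima (default two), with per-pose
  observables — macrodipole (μ = 4.8032 Σ qᵢ(rᵢ−r₀) Debye), dipole angle
  to the surface normal, cofactor-to-surface distances, Kabsch RMSD.
* **Dipole–field re-ranking** S = E + w(−μ⃗·E⃗) with the field sign set
  by the applied potential relative to the PZC (−0.25 V) — the
  qualitative driver of potential-induced re-orientation.
* **Directional statistics** of dipole pseudo-trajectories (circular
  spread √(−2 ln R̄)) and **surface coverage** estimates (hexagonal disk
  packing; de Feijter ellipsometric conversion).
* **Synthetic generators** (dumbbells, patchy spheres, planted two-basin
  landscapes, von Mises–Fisher dipole trajectories) with closed-form
  ground truth, so the whole pipeline is testable offline.

## Worked example

A 200-atom sphere carrying a −1 e charge patch ("cap") screened over a
10×10 slab whose 8 protonated headgroups carry +8 e:

```r
library(samscan)
protein   <- make_patchy_sphere()                          # -1 e cap toy
surface   <- build_sam_surface(surface_spec(nx = 10, ny = 10))
landscape <- scan_orientations(protein, surface, scan_config())
print(landscape)
#> <energy_landscape: 36 x 36 orientations, E in [-131.38, -5.57] kcal/mol>
poses <- select_minima(landscape)
for (p in poses) print(p)
#> <pose: theta 0, psi 190, E -131.381 kcal/mol>
#> <pose: theta 180, psi 0, E -130.572 kcal/mol>
```

The global minimum rotates the charged cap to face the oppositely charged
surface (ψ = 190° maps the cap axis to z = −0.985), and the two selected
poses are the two mutually separated basins of the landscape — the two
candidate adsorption orientations.  The numbered scripts under
`analysis/` run this screen end to end and add the dipole-fluctuation and
coverage analyses, writing tables under `results/`:

```sh
Rscript analysis/01_surface_protonation.R
Rscript analysis/02_orientation_landscape.R
Rscript analysis/03_favorable_orientations.R
Rscript analysis/04_dipole_fluctuation.R
Rscript analysis/05_surface_coverage.R
```

For a real structure, point `run_pipeline()` at a YAML config with a
`structure: {path: your.pdb}` section (optionally a `cterm_sequence` for
an unresolved C-terminal tail and per-atom `hetero_charges` for
cofactors); the pipeline writes the landscape (CSV/JSON), the posed
structures (multi-MODEL PDB) and a JSON run report, bit-identically for a
fixed config and seed.

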