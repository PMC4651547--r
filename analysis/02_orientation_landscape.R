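#!/usr/bin/env Rscript
# Construct the (theta, psi) interaction-energy landscape of a charged
# rigid body over the partially protonated SAM.  The protein here is the
# synthetic patchy sphere (a 200-atom shell carrying a -1 e charge patch):
# a stand-in with known ground truth, since the real heterodimer's
# coordinates are an external input.  Orientations are sampled in 10-degree
# steps over the full torus with the body placed 5 Angstrom above the SAM.

suppressPackageStartupMessages(library(samscan))
dir.create("results", showWarnings = FALSE)

protein <- make_patchy_sphere()          # -1 e cap, 60 deg half-angle
surface <- build_sam_surface(surface_spec(nx = 10, ny = 10))  # +8 e slab
cfg <- scan_config()                     # 10 deg steps, 5 A gap, in vacuo

landscape <- scan_orientations(protein, surface, cfg)
print(landscape)
write_landscape_csv(landscape, "results/landscape.csv")
write_landscape_json(landscape, "results/landscape.json")

idx <- which(landscape$energies == min(landscape$energies), arr.ind = TRUE)
cat(sprintf("global minimum %.2f kcal/mol at theta = %g, psi = %g\n",
            min(landscape$energies),
            landscape$theta_values[idx[1]], landscape$psi_values[idx[2]]))
capdir <- drop(rotation_matrix(landscape$theta_values[idx[1]],
                               landscape$psi_values[idx[2]]) %*% c(0, 0, 1))
cat(sprintf("rotated charge-patch axis z-component: %.3f (cap faces the surface)\n",
            capdir[3]))
cat("wrote results/landscape.csv and results/landscape.json\n")
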