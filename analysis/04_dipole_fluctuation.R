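#!/usr/bin/env Rscript
# Directional statistics of dipole pseudo-trajectories.  Surface adsorption
# is reported to pin the enzyme's dipole direction (smaller directional
# fluctuation) while its magnitude grows; here two von Mises-Fisher
# pseudo-trajectories with known concentrations emulate the free and the
# adsorbed regime, and the circular-spread estimator is checked against the
# closed-form expectation for each.

suppressPackageStartupMessages(library(samscan))
dir.create("results", showWarnings = FALSE)

cases <- data.frame(regime = c("free_in_solution", "surface_adsorbed"),
                    kappa = c(20, 400),
                    magnitude_debye = c(500, 700))

rows <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
  traj <- make_vmf_dipole_trajectory(1000, kappa = cases$kappa[i],
                                     magnitude = cases$magnitude_debye[i],
                                     seed = i)
  st <- trajectory_dipole_stats(traj)
  data.frame(regime = cases$regime[i], kappa = cases$kappa[i],
             n_frames = st$n_frames,
             angular_spread_deg = st$angular_spread,
             expected_spread_deg = vmf_expected_spread(cases$kappa[i]),
             magnitude_mean_debye = st$magnitude_mean,
             magnitude_sd_debye = st$magnitude_sd)
}))
write.csv(rows, "results/dipole_fluctuation.csv", row.names = FALSE)
print(rows, digits = 4)
cat("adsorption-like concentration narrows the spread by",
    sprintf("%.1fx\n", rows$angular_spread_deg[1] / rows$angular_spread_deg[2]))
cat("wrote results/dipole_fluctuation.csv\n")
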