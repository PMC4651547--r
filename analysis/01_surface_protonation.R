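#!/usr/bin/env Rscript
# Build the SAM-coated Au slab used throughout the analysis and record its
# protonation state.  At pH 7 an amino-hexanethiol monolayer with a surface
# pKa near 6 carries a protonated (-NH3+) headgroup on roughly 8% of its
# chains; the default slab realises that fraction exactly (56 of 700).

suppressPackageStartupMessages(library(samscan))
dir.create("results", showWarnings = FALSE)

surface <- build_sam_surface()
n_chains <- surface$spec$nx * surface$spec$ny
print(surface)

summary <- data.frame(
  n_chains = n_chains,
  n_protonated = length(surface$protonated_indices),
  protonated_pct = 100 * length(surface$protonated_indices) / n_chains,
  net_charge_e = surface$net_charge,
  extent_x_A = surface$extent_x,
  extent_y_A = surface$extent_y,
  top_z_A = surface$top_z)
write.csv(summary, "results/surface_summary.csv", row.names = FALSE)

# Henderson-Hasselbalch curve across the pKa uncertainty band (6.0 +/- 0.2)
curve <- expand.grid(pH = seq(4, 10, by = 0.1), pKa = c(5.8, 6.0, 6.2))
curve$protonated_fraction <- protonated_fraction(curve$pH, curve$pKa)
write.csv(curve, "results/protonation_curve.csv", row.names = FALSE)

cat(sprintf("pH 7, pKa 6.0: %.4f protonated; pKa 5.94 gives %.3f (the 8%% assumption)\n",
            protonated_fraction(7, 6), protonated_fraction(7, 5.94)))
cat("wrote results/surface_summary.csv and results/protonation_curve.csv\n")
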