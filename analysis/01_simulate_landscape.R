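#!/usr/bin/env Rscript

# Stage 1 - build the synthetic study system.
#
# A 12-km2-scale landscape sampled on a 215-m grid plus 30 random sites
# (269 retained, ~16% forest), with spatially autocorrelated soil
# properties, daily climate for the 2010-2016 farming years, 2004-2016
# plot-level operation logs drifting from a plowing-dominated regime to a
# reduced-tillage / higher-pesticide regime, and microbial responses
# (biomass- and richness-like) generated from known path-coefficient
# structures. Everything downstream reads the tables written here.

library(soilscape)

seed <- 101
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

land <- simulate_landscape(seed = seed)
print(land)

for (nm in c("sites", "soil", "climate", "operations", "applications",
             "indicators", "campaign_table", "model_table")) {
  write.csv(land[[nm]], file.path(outdir, paste0(nm, ".csv")),
            row.names = FALSE)
}
jsonlite::write_json(
  list(seed = seed,
       smmb_path_matrix = land$truth$path_matrix,
       richness_path_matrix = land$richness_truth$path_matrix,
       noise_sd = land$truth$noise_sd),
  file.path(outdir, "truth.json"), matrix = "rowmajor", digits = NA)

ct <- land$campaign_table
cat(sprintf("sites: %d (%d forest) | plot-years: %d | campaigns: %s\n",
            nrow(land$sites), sum(land$sites$land_use == "forest"),
            nrow(land$operations),
            paste(unique(ct$campaign), collapse = ", ")))
cat(sprintf("cropland SOC mean %.1f g/kg, forest %.1f g/kg (2011)\n",
            mean(ct$SOC[ct$campaign == 2011 & ct$land_use == "cropland"]),
            mean(ct$SOC[ct$campaign == 2011 & ct$land_use == "forest"])))
cat("tables written under", outdir, "\n")
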