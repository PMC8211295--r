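#!/usr/bin/env Rscript

# Stage 5 - the campaign-comparison table: mean +- SE of each variable at
# the landscape, forest and cropland scales, with paired Wilcoxon
# signed-rank tests of the 2011 vs 2016 change (stars: . <0.1, * <0.05,
# ** <0.01, *** <0.001).

library(soilscape)

ct <- read.csv("results/data/campaign_table.csv")

vars <- c("smmb", "richness", "water_stress", "SOC", "TN", "CN", "pH",
          "OM", "Freq_winter", "Freq_spring", "nbr_species",
          "Freq_plowing", "Freq_tillage", "TFI_herbicide",
          "TFI_fungicide", "TFI_total", "N", "P", "K", "Mg", "S")
tab <- do.call(rbind, lapply(intersect(vars, names(ct)), function(v) {
  summarize_by_scale(ct, v)
}))
write.csv(tab, "results/summary_table.csv", row.names = FALSE)

fmt <- tab
for (cc in c("mean_2011", "se_2011", "mean_2016", "se_2016")) {
  fmt[[cc]] <- sprintf("%.2f", fmt[[cc]])
}
print(fmt[, c("variable", "scale", "mean_2011", "se_2011", "mean_2016",
              "se_2016", "stars")], row.names = FALSE)
cat("summary written to results/summary_table.csv\n")
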