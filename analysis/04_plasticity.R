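#!/usr/bin/env Rscript
## Stage 4 — plasticity phenotypes.
## Cell means, the environmental quality index, Finlay-Wilkinson slope and
## VAR per line, covariate selection, and the factorial-regression
## sensitivity SCv.

library(magicmet)
sim <- readRDS("scratch/sim.rds")
corrected <- readRDS("scratch/corrected.rds")

cells <- cell_means(corrected, "fw")
pt <- plasticity_table(cells, sim$env_specs)
write.csv(pt, "results/plasticity.csv", row.names = FALSE)
selection <- attr(pt, "covariate_selection")
write.csv(selection, "results/covariate_selection.csv", row.names = FALSE)
saveRDS(list(cells = cells, plasticity = pt), "scratch/plasticity.rds")

best <- pt$best_covariate[1]
message(sprintf("best covariate: %s (share of GxE SS: %.2f); slope range %.2f-%.2f",
                best,
                selection$ss_share[selection$covariate == best],
                min(pt$slope, na.rm = TRUE), max(pt$slope, na.rm = TRUE)))
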