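#!/usr/bin/env Rscript
## Stage 5 — Haley-Knott scans for the genotypic mean and the three
## plasticity phenotypes, with the genome-wide -log10(alpha/#markers)
## threshold, 2-LOD peak separation and 1-LOD confidence intervals.

library(magicmet)
sim <- readRDS("scratch/sim.rds")
pl <- readRDS("scratch/plasticity.rds")

scans <- scan_all_phenotypes(sim$tensor, pl$plasticity, sim$map,
                             alpha = 0.05, trait = "fw")
all_peaks <- do.call(rbind, lapply(names(scans), function(ph) {
  pk <- scans[[ph]]$peaks
  if (nrow(pk)) cbind(trait = "fw", phenotype = ph, pk) else NULL
}))
if (is.null(all_peaks)) all_peaks <- data.frame()
write.csv(all_peaks, "results/peaks.csv", row.names = FALSE)
for (ph in names(scans))
  write.csv(scan_to_table(scans[[ph]], sim$map),
            sprintf("results/scan_%s.csv", ph), row.names = FALSE)
saveRDS(scans, "scratch/scans.rds")

message(sprintf("threshold %.2f; peaks per phenotype: %s",
                scans[[1]]$threshold,
                paste(names(scans),
                      vapply(scans, function(s) nrow(s$peaks), 0L),
                      sep = "=", collapse = ", ")))
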