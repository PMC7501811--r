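#!/usr/bin/env Rscript
## Stage 7 — cross-result synthesis.
## Environment clustering, QTL category overlap across mean/plasticity/QEI,
## chromosome enrichment of plasticity QTLs, allelic-effect concordance of
## co-locating mean and plasticity peaks, and selective-sweep intersection
## against a bundled synthetic sweep set.

library(magicmet)
sim <- readRDS("scratch/sim.rds")
scans <- readRDS("scratch/scans.rds")
qei <- readRDS("scratch/qei.rds")

cl <- cluster_environments(sim$env_specs, k = 4)
write.csv(data.frame(env = names(cl), cluster = as.integer(cl)),
          "results/env_clusters.csv", row.names = FALSE)

## QEI records as point intervals at their marker positions
qei_peaks <- NULL
if (nrow(qei$records)) {
  i <- match(qei$records$marker[qei$records$significant], sim$map$marker)
  if (length(i))
    qei_peaks <- data.frame(marker = sim$map$marker[i],
                            chrom = sim$map$chrom[i], bp = sim$map$bp[i],
                            ci_lo_bp = pmax(1, sim$map$bp[i] - 5e5),
                            ci_hi_bp = sim$map$bp[i] + 5e5)
}
catalog <- qtl_catalog(c(lapply(scans, function(s) s$peaks),
                         list(qei = qei_peaks)), trait = "fw")
ov <- overlap_qtls(catalog)
write.csv(ov$unique_qtls, "results/unique_qtls.csv", row.names = FALSE)

plast <- catalog$category %in% c("slope", "var", "scv")
enr <- if (sum(plast) >= 2)
  chisq_chromosome_enrichment(catalog$chrom[plast], sim$map) else NULL
if (!is.null(enr))
  write.csv(enr$table, "results/enrichment.csv", row.names = FALSE)

## concordance between the top mean peak and the top plasticity peak
conc <- NULL
mean_pk <- scans$mean$peaks
pl_pk <- do.call(rbind, lapply(scans[c("slope", "var", "scv")],
                               function(s) s$peaks))
if (nrow(mean_pk) && !is.null(pl_pk) && nrow(pl_pk)) {
  a <- unlist(mean_pk[which.max(mean_pk$lod), sprintf("F%d", 1:8)])
  b <- unlist(pl_pk[which.max(pl_pk$lod), sprintf("F%d", 1:8)])
  conc <- allelic_effect_concordance(a, b)
}

sweeps <- read_sweeps_bed(system.file("extdata", "synthetic_sweeps.bed",
                                      package = "magicmet"))
sw <- intersect_sweeps(catalog, sweeps)
write.csv(sw$table, "results/sweep_overlap.csv", row.names = FALSE)

summary <- list(
  n_environment_clusters = length(unique(cl)),
  n_peaks = nrow(catalog), n_unique_qtls = nrow(ov$unique_qtls),
  category_counts = as.list(ov$counts),
  enrichment_p = if (!is.null(enr)) enr$p else NA,
  concordance = conc,
  sweep_fraction_inside = sw$fraction_inside)
jsonlite::write_json(summary, "results/integration_summary.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

message(sprintf("%d peaks -> %d unique QTLs; %.0f%% of filtered QTLs inside sweeps",
                nrow(catalog), nrow(ov$unique_qtls),
                100 * sw$fraction_inside))
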