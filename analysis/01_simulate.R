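#!/usr/bin/env Rscript
## Stage 1 — simulate the synthetic MAGIC-MET trial.
##
## 400 8-way MAGIC lines (three selfing generations), 12 chromosomes-worth
## of markers scaled to desk size (6 chromosomes x 24 markers), grown in 12
## environments from four climatic clusters, two replicates per line plus
## four control lines. The genetic architecture plants three QTLs: a pure
## mean-effect locus, a locus with founder-by-environment interaction, and
## a locus whose founder effects respond to the Vpd covariate.

library(magicmet)

dir.create("results", showWarnings = FALSE)
seed <- 20260929L

envs <- default_environments(seed = 42L)
chrs <- data.frame(chrom = as.character(1:6),
                   length_morgan = c(1.2, 1, 1, 0.9, 0.8, 0.8),
                   length_bp = c(9.8e7, 8.3e7, 6.5e7, 6.4e7, 6.5e7, 4.6e7))
qtls <- list(
  qtl_spec("2", 40, main_effects = 0.6 * c(1, 1, 1, 1, -1, -1, -1, -1)),
  qtl_spec("4", 55, env_effects = 0.5 * outer(c(1, -1, 1, -1, 1, -1, 1, -1),
                                              rep_len(c(1, -1), 12))),
  qtl_spec("5", 30, covariate = "Vpd",
           sensitivity = 0.5 * c(1, 1, -1, -1, 1, -1, 1, -1)))

cfg <- sim_config(n_lines = 400, chromosomes = chrs,
                  markers_per_chromosome = 24, env_specs = envs,
                  qtl_specs = qtls, n_replicates = 2, n_controls = 4,
                  mu = 10, sigma2_L = 0.6, sigma2_LxE = 0.3,
                  prob_softening = 0.03, seed = seed)
sim <- simulate_magic_met(cfg, trait = "fw")
write_simulated_data(sim, "results/simulated")
saveRDS(sim, "scratch/sim.rds")   # binary cache for later stages only

message(sprintf("simulated %d lines x %d markers x %d environments (%d records)",
                dim(sim$tensor)[1], dim(sim$tensor)[2], nrow(envs),
                nrow(sim$phenotypes)))
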