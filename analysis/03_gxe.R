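#!/usr/bin/env Rscript
## Stage 3 — whole-design variance decomposition.
## REML fit with random line and line-by-environment effects and
## per-environment residual variances; reports prop.sigma2_GxE, H2 and the
## G-by-E likelihood-ratio test.

library(magicmet)
corrected <- readRDS("scratch/corrected.rds")

vt <- varcomp_table(corrected, "fw")
write.csv(vt, "results/varcomp.csv", row.names = FALSE)

message(sprintf("fw: sigma2_L=%.3f sigma2_LxE=%.3f prop.GxE=%.3f H2=%.3f (LRT p=%.2g)",
                vt$sigma2_L, vt$sigma2_LxE, vt$prop_gxe, vt$H2, vt$lrt_p))
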