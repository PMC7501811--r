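#!/usr/bin/env Rscript
## Run the whole MAGIC-MET analysis end to end: simulate a 12-environment
## synthetic trial, correct it, decompose variance, estimate plasticity,
## scan for QTLs, detect QTL-by-environment interactions, and integrate.
## Each stage writes its tables under results/ and can also be run alone.

for (f in sprintf("analysis/%02d_%s.R", 1:7,
                  c("simulate", "correct", "gxe", "plasticity", "scan",
                    "qei", "integrate")))
  source(f, echo = FALSE)
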