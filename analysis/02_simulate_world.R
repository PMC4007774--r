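#!/usr/bin/env Rscript
# Simulate the default synthetic world: 221-primitive hierarchy, a
# poly-hierarchic terminology with manual + inheritable alignments, a
# mono-hierarchic terminology aligned with a 25% per-pair discordance
# rate, and partial cross-links. Writes the TSV inputs consumed by
# 03_evaluate_agreement.R.

library(iconcord)

cfg <- synthetic_config(seed = 20260923)
world <- generate_world(cfg)
print(world)

write_world(world, "results/world")
cat("world written to results/world/\n")
cat(sprintf("  manual alignment records (poly side): %d\n",
            nrow(world$term_a$alignments)))
cat(sprintf("  cross-linked pairs: %d, of which %d perturbed (rate %.2f)\n",
            nrow(world$truth), sum(world$truth$perturbed),
            cfg$discordance_rate))
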