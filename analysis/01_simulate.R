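#!/usr/bin/env Rscript
# Stage 1 — simulate the border mass-trapping trial.
#
# Generates the default synthetic orchard trial (800 m border, four
# alternating trap/control plots, 8 pheromone traps 7 m outside the
# border, 100 assessment points, 6 assessment dates) and persists every
# pipeline input as plain text under results/trial/.

suppressMessages(library(bordertrap))

scenario <- orchard_scenario(seed = 42)
trial <- generate_trial(scenario)
write_trial(trial, "results/trial")

cat("Simulated trial written to results/trial/\n")
cat(sprintf("  %d assessment points over %d plots (%d trapped)\n",
            nrow(trial$points), length(unique(trial$points$plot_id)),
            length(unique(trial$points$plot_id[trial$points$has_traps]))))
cat(sprintf("  %d traps, %d catch records, %d dates\n",
            nrow(trial$traps), nrow(trial$catches),
            length(unique(trial$catches$date))))
cat(sprintf("  total fruit scored: %d\n",
            sum(trial$points[, paste0("n_class", 1:6)])))
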