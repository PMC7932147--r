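#!/usr/bin/env Rscript
# Stage 1 — simulate the posthypoxic cohort with known ground truth.
#
# Builds the synthetic study: plasma and retina 39-plex Luminex plates
# (three groups x 5 mice, duplicate wells, Chex control beads, the
# published 1h fold effects as ground truth), the paired OCT thickness
# table (8 eyes in the 1h cohort, 10 in the 18h cohort) and the
# per-animal histology table. Writes the raw tables under results/data/.

library(posthypoxia)

seed <- 1L
out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
message("simulation seed: ", seed)

cfg <- run_config(seed = seed)

plasma <- simulate_luminex_plate(cfg$plasma_config)
retina <- simulate_luminex_plate(cfg$retina_config)
write_plate(plasma, file.path(out_dir, "plate_plasma.tsv"))
write_plate(retina, file.path(out_dir, "plate_retina.tsv"))
cat(sprintf("plasma plate: %d wells (%d samples x 2 duplicates)\n",
            nrow(plasma), nrow(plasma) / 2))
cat(sprintf("retina plate: %d wells; ground-truth 1h effects: %d plasma, %d retina analytes (%d shared)\n",
            nrow(retina), nrow(default_plasma_effects()),
            nrow(default_retina_effects()),
            length(intersect(default_plasma_effects()$analyte,
                             default_retina_effects()$analyte))))

oct <- simulate_oct_table(cfg$plasma_config)
utils::write.table(oct, file.path(out_dir, "oct_thickness.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("OCT table: %d rows (%d eyes, baseline + posthypoxia)\n",
            nrow(oct), nrow(oct) / 2))

hist_tab <- simulate_histology(cfg$plasma_config)
utils::write.table(hist_tab, file.path(out_dir, "histology.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("histology table: %d animals across %d groups\n",
            nrow(hist_tab), length(unique(hist_tab$group))))
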