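#!/usr/bin/env Rscript
# Build the synthetic study assemblage: four ordered phases with graded
# latent centroid shifts, U-shaped dispersion (phases 1 and 4 more
# heterogeneous than 2 and 3), dolerite-dominant raw materials and 8%
# MCAR missingness, at one tenth of the reference sample sizes
# (76/169/59/147 per phase).  Writes the table, the generating truth and
# per-variable summaries under results/simulated/.

library(morphodist)

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- assemblage_config(
  n_per_group = c(76, 169, 59, 147),
  shift_per_group = 0.35,
  dispersion_scale_per_group = c(1.25, 1.0, 1.0, 1.25),
  missing_rate = 0.08,
  seed = 1
)
sim <- simulate_assemblage(cfg)

write_flake_table(sim$table, file.path(out, "assemblage.csv"))
jsonlite::write_json(
  list(group_means = sim$truth$group_means,
       dispersion = sim$truth$dispersion,
       thresholds = sim$truth$thresholds),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
write_flake_summary(summarize_flakes(sim$table), out)

counts <- table(sim$table$group)
message("simulated ", nrow(sim$table), " flakes (",
        paste(sprintf("phase %s: %d", names(counts), as.integer(counts)),
              collapse = ", "), ")")
message("missing cells: ",
        sum(is.na(sim$table[, sibhudu_schema()$name])),
        sprintf(" (%.1f%%)", 100 * mean(is.na(
          as.matrix(sim$table[, sibhudu_schema()$name])))))
message("written to ", out)
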