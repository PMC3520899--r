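#!/usr/bin/env Rscript

# Step 1 — simulate the arrayed library screen.
#
# Generates the full 205-plate synthetic screen (4 mock + 4 empty-vector
# control wells in column 12 of every plate, 88 sample wells drawn from
# the failed/low/typical/high titer mixture) together with its ground
# truth, and writes both tables under results/library/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressMessages(library(titerscreen))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 101L
out <- "results/library"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- plate_sim_config(seed = seed)
sim <- generate_plate_set(cfg)

write_screen_csv(sim$plates, file.path(out, "plates.csv"))
write_screen_csv(sim$truth, file.path(out, "plate_truth.csv"))
write_run_config(list(seed = seed, n_plates = cfg$n_plates,
                      package = "titerscreen",
                      version = as.character(packageVersion("titerscreen"))),
                 file.path(out, "simulate_config.txt"))

n_sample <- sum(sim$plates$role == "sample")
cat(sprintf("Simulated %d plates (%d sample wells, %d mock, %d vector).\n",
            cfg$n_plates, n_sample,
            sum(sim$plates$role == "mock"), sum(sim$plates$role == "vector")))
cat(sprintf("True component mix: %s.\n",
            paste(sprintf("%s %.1f%%", names(table(sim$truth$component)),
                          100 * table(sim$truth$component) / n_sample),
                  collapse = ", ")))
cat("Wrote", file.path(out, "plates.csv"), "and ground truth.\n")
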