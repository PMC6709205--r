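#!/usr/bin/env Rscript
# Step 1: simulate the synthetic study population.
#
# Draws the default 20-animal x 10-cell population (log-normal calcium
# influx across cells; normal pump/indicator variation), simulates the
# standard sweep (25 APs at 50 Hz after 5 s of baseline, three repeats per
# cell), and stores the ground-truth parameter table plus one example
# line-scan recording. Downstream steps quantify these recordings blind to
# the ground truth.

suppressPackageStartupMessages(library(catrace))

out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

spec <- population_spec(n_animals = 20, cells_per_animal = 10, seed = 1)
truth <- draw_population_params(spec)
write.csv(truth, file.path(out, "ground_truth_parameters.csv"), row.names = FALSE)
cat(sprintf("drew %d cells from %d animals (%d litters)\n",
            nrow(truth), length(unique(truth$animal)),
            length(unique(truth$litter))))

# one full-resolution example recording, stored as TIFF + JSON sidecar
row <- truth[1, ]
p <- catrace:::.params_from_row(row)
rec <- simulate_cell_recordings(p, default_protocol(), seed = row$noise_seed,
                                labels = list(cell = row$cell_id,
                                              animal = row$animal,
                                              litter = row$litter,
                                              sex = row$sex,
                                              condition = "baseline"))[[1]]
paths <- write_linescan(rec, file.path(out, "example_linescan"))
cat("example recording:", paths["tif"], "+ sidecar\n")
cat(sprintf("  %d px x %d samples, %.2f s sweep, stimulus %d pulses at %g Hz\n",
            nrow(rec$intensity), ncol(rec$intensity),
            ncol(rec$intensity) * rec$sampling_interval,
            rec$stimulus$n_pulses, rec$stimulus$pulse_frequency))
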