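#!/usr/bin/env Rscript
# Estimate the distant-field flow speed from the particle frame pair of
# step 01 by mutual-nearest-neighbour tracking of blob centroids.

suppressMessages(library(pocketcav))

stopifnot(file.exists("results/phantoms/particle_pair.tif"))
pair <- read_frame_stack("results/phantoms/particle_pair.tif",
                         frame_interval_us = 10, pixel_size_um = 20)
ve <- estimate_velocity(pair$frames[[1]], pair$frames[[2]],
                        pixel_size_um = pair$pixel_size_um,
                        frame_interval_us = pair$frame_interval_us,
                        detection_threshold = 0.4)
print(ve)
cat(sprintf("unmatched: %d in frame A, %d in frame B\n",
            ve$n_unmatched_a, ve$n_unmatched_b))
write.csv(ve$matches, "results/velocities.csv", row.names = FALSE)
cat("wrote results/velocities.csv\n")
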