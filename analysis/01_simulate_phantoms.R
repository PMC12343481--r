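#!/usr/bin/env Rscript
# Generate the synthetic inputs used by the downstream analysis steps:
# a high-speed cavitation video phantom (with ground truth), a pair of
# stained-monolayer micrographs (control + treated), and a particle
# displacement frame pair. Everything is seeded and written under results/.

suppressMessages(library(pocketcav))

dir.create("results/phantoms", recursive = TRUE, showWarnings = FALSE)

## cavitation video: 128 x 256 px, 20 um/px, 10 us frames, noise-free
cfg <- phantom_config(seed = 1, noise_sigma = 0)
ph <- make_cavitation_sequence(cfg)
write_frame_stack(ph$sequence, "results/phantoms/cavitation_stack.tif")
write_frame_stack(ph$truth$pb_masks, "results/phantoms/truth_pb_masks.tif")
write_frame_stack(ph$truth$sc_masks, "results/phantoms/truth_sc_masks.tif")
write.csv(data.frame(
  frame_index = seq_along(ph$truth$pb_area_mm2),
  time_us = frame_times_us(ph$sequence),
  true_A_PB_mm2 = ph$truth$pb_area_mm2,
  true_A_SC_mm2 = ph$truth$sc_area_mm2
), "results/phantoms/truth_areas.csv", row.names = FALSE)
write_config(cfg[setdiff(names(cfg), character(0))],
             "results/phantoms/cavitation_config.yml")
cat(sprintf("cavitation phantom: %d frames, peak true A_PB = %.3f mm^2\n",
            cfg$n_frames, max(ph$truth$pb_area_mm2)))

## micrographs at 63x-like sampling (0.103 um/px): control and treated
mcfg <- function(seed) phantom_config(seed = seed, image_height_px = 400,
                                      image_width_px = 400,
                                      pixel_size_um = 0.103)
control <- make_micrograph(mcfg(10), n_cells = 100, touching_fraction = 0.1)
treated <- make_micrograph(mcfg(11), n_cells = 40, touching_fraction = 0.1)
invisible(tiff::writeTIFF(control$image,
  "results/phantoms/micrograph_control.tif", bits.per.sample = 8L))
invisible(tiff::writeTIFF(treated$image,
  "results/phantoms/micrograph_treated.tif", bits.per.sample = 8L))
write.csv(rbind(cbind(image = "control", control$truth$centers),
                cbind(image = "treated", treated$truth$centers)),
          "results/phantoms/micrograph_centers.csv", row.names = FALSE)
cat(sprintf("micrographs: control %d cells, treated %d cells\n",
            control$truth$total, treated$truth$total))

## particle frame pair: uniform 10 m/s flow (5 px/frame at this calibration)
vcfg <- phantom_config(seed = 12, noise_sigma = 0)
pp <- make_particle_pair(vcfg, n_particles = 20, velocity_m_s = c(10, 0))
write_frame_stack(list(pp$frame_a, pp$frame_b),
                  "results/phantoms/particle_pair.tif")
cat(sprintf("particle pair: %d particles, true displacement (%g, %g) px\n",
            nrow(pp$truth$positions), pp$truth$displacement_px["dx"],
            pp$truth$displacement_px["dy"]))
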