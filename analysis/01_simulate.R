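#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study data.
#
# Builds the reference graded dataset: a 200-voxel ROI with a planted
# one-dimensional graded mixing field between two band-limited latent
# network signals (10 subjects x 2 runs x 300 frames, TR 0.72 s, noise sd
# 0.5), and a 100-study coordinate database whose in-ROI foci follow the
# same field and whose term frequencies are coupled to the two networks.
# Writes the coordinate database, the ROI mask and the ground-truth weights
# under results/data/.

suppressPackageStartupMessages(library(gradparc))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(structure = "graded_1d", seed = 1L)
sim <- simulate_timeseries(cfg)
cdb <- simulate_coordinate_db(cfg, sim$roi)

write_volume(sim$roi$vol, file.path(out, "roi_mask.nii.gz"))
write_coordinate_db(cdb$db, file.path(out, "foci.tsv"),
                    file.path(out, "term_frequencies.tsv"))
write.table(cdb$truth$annotation, file.path(out, "term_annotation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(voxel = seq_len(sim$roi$n_voxels),
                       w1 = sim$truth$w1, w2 = sim$truth$w2),
            file.path(out, "ground_truth_weights.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in seq_along(sim$subjects)) {
  for (r in seq_along(sim$subjects[[s]])) {
    write_volume(sim$subjects[[s]][[r]],
                 file.path(out, sprintf("sub%02d_run%d.nii.gz", s, r)))
  }
}

cat(sprintf("simulated %d subjects x %d runs (%d frames) over %d voxels\n",
            cfg$n_subjects, cfg$n_runs, cfg$n_timepoints,
            prod(cfg$dims)))
cat(sprintf("coordinate database: %d studies, %d foci, %d terms\n",
            nrow(cdb$db$studies), nrow(cdb$db$foci), ncol(cdb$db$terms)))
cat("wrote", out, "\n")
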