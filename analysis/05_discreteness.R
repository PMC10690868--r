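#!/usr/bin/env Rscript

# Stage 5: graded-versus-discrete detection.
#
# Re-runs the task-free branch on a blocked (two_block) and a graded
# (graded_1d) configuration and compares the normalized algebraic
# connectivity and the gradient-value gap diagnostic. This analysis runs
# without spatial smoothing: smoothing across a planted hard boundary
# manufactures local gradation and inflates the index, so boundary
# detection is evaluated on unsmoothed data.

suppressPackageStartupMessages(library(gradparc))

out <- "results/discreteness"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

branch <- function(structure, seed) {
  cfg <- synthetic_config(structure = structure, seed = seed)
  sim <- simulate_timeseries(cfg)
  pp <- preprocess_params(gsr = FALSE, smooth = FALSE, band_pass = TRUE,
                          tr = cfg$tr)
  mats <- lapply(sim$subjects, function(runs)
    lapply(runs, function(r)
      timeseries_similarity(preprocess_run(r, sim$roi, pp), sim$roi)))
  R <- aggregate_similarity(mats)$group
  gs <- embed_similarity(R, top_pct = 10, n_components = 2)
  list(index = as.numeric(gradation_index(R)),
       gap_ratio = gradient_gap_ratio(gs$embedding[, 1]),
       top_pct_used = gs$top_pct_used)
}

blocked <- branch("two_block", 7L)
graded <- branch("graded_1d", 7L)

cat(sprintf("two_block : index %.3f, gradient-1 gap ratio %.1f (sparsity used: %d%%)\n",
            blocked$index, blocked$gap_ratio, blocked$top_pct_used))
cat(sprintf("graded_1d : index %.3f, gradient-1 gap ratio %.1f (sparsity used: %d%%)\n",
            graded$index, graded$gap_ratio, graded$top_pct_used))
cat("a hard boundary shows a near-zero index and a dominant gradient gap;\n")
cat("graded organization shows a high index and no comparably dominant gap\n")

jsonlite::write_json(list(two_block = blocked, graded_1d = graded),
                     file.path(out, "summary.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
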