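#!/usr/bin/env Rscript

# Stage 4: functional characterization of the gradient extremes.
#
# Extracts the 20% lowest/highest-gradient voxel clusters from the leading
# task-free gradient, contrasts their seed-based resting-state FC with
# paired t-tests (masked by the clusters' own FWE-significant one-sample
# connectivity), runs ALE contrasts between the clusters' MACM study
# selections, computes overlap percentages with a reference network atlas,
# and decodes both clusters against the term table (chi-square forward /
# reverse inference, BH-FDR at 0.05, cognitive-likelihood filter at 0.8).

suppressPackageStartupMessages(library(gradparc))

data_dir <- "results/data"
out <- "results/characterization"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

roi <- roi_mask(read_volume(file.path(data_dir, "roi_mask.nii.gz")))
db <- read_coordinate_db(file.path(data_dir, "foci.tsv"),
                         file.path(data_dir, "term_frequencies.tsv"))
annotation <- read.table(file.path(data_dir, "term_annotation.tsv"),
                         header = TRUE)
gvals <- read.table("results/taskfree/gradient_values.tsv", header = TRUE)

ext <- extreme_clusters(gvals$gradient1, pct = 20)
seed_low <- roi_to_volume(as.numeric(seq_len(roi$n_voxels) %in% ext$low), roi)
seed_high <- roi_to_volume(as.numeric(seq_len(roi$n_voxels) %in% ext$high), roi)
write_volume(seed_low, file.path(out, "cluster_low.nii.gz"))
write_volume(seed_high, file.path(out, "cluster_high.nii.gz"))
cat(sprintf("gradient-extreme clusters: %d voxels per tail\n",
            length(ext$low)))

## seed-based resting-state FC contrasts -------------------------------------
pp <- preprocess_params(gsr = FALSE, smooth = TRUE, band_pass = TRUE, tr = 0.72)
n_sub <- length(Sys.glob(file.path(data_dir, "sub*_run1.nii.gz")))
subj_series <- lapply(seq_len(n_sub), function(s) {
  files <- Sys.glob(file.path(data_dir, sprintf("sub%02d_run*.nii.gz", s)))
  do.call(cbind, lapply(files, function(f)
    roi_timeseries(preprocess_run(read_volume(f), roi, pp), roi)))
})
zmaps <- function(cluster) t(vapply(subj_series, function(Y)
  seed_glm(Y, seed_series(list(Y), cluster)), numeric(roi$n_voxels)))
z_low <- zmaps(ext$low); z_high <- zmaps(ext$high)
t_high <- group_one_sample_t(z_high)
t_low <- group_one_sample_t(z_low)
t_pair <- group_paired_t(z_high, z_low)
thr_high <- fwe_voxel_threshold(t_high, 0.05, "bonferroni")
thr_low <- fwe_voxel_threshold(t_low, 0.05, "bonferroni")
masked_hi <- mask_contrast(t_pair$t, thr_high$t_masked)
masked_lo <- mask_contrast(-t_pair$t, thr_low$t_masked)
write_volume(roi_to_volume(masked_hi, roi),
             file.path(out, "contrast_high_gt_low_masked.nii.gz"))
write_volume(roi_to_volume(masked_lo, roi),
             file.path(out, "contrast_low_gt_high_masked.nii.gz"))
cat(sprintf("FC contrast: %d voxels high>low, %d voxels low>high (masked)\n",
            sum(masked_hi > 0), sum(masked_lo > 0)))

## conjunction of the clusters' significant connectivity ---------------------
conj <- conjunction(thr_high$t_masked, thr_low$t_masked)
cat(sprintf("conjunction of significant cluster FC: %d voxels\n", sum(conj)))

## MACM contrast between the clusters ----------------------------------------
grid <- grid_for_db(db, roi, spacing_mm = 4)
ids_high <- select_studies_in_mask(db, seed_high)
ids_low <- select_studies_in_mask(db, seed_low)
cat(sprintf("studies activating the clusters: %d (high), %d (low)\n",
            length(ids_high), length(ids_low)))
mac_high <- macm_seed(db, seed_high, grid, threshold = TRUE, n_iter = 500,
                      seed_rng = 11L)
contrast <- ale_contrast(db, ids_high, ids_low, grid, n_perm = 500, seed = 12L)
masked_macm <- ifelse(mac_high$thresholded > 0 & contrast$contrast > 0,
                      contrast$contrast, 0)
cat(sprintf("MACM contrast (high>low, FWE-masked): %d grid voxels\n",
            sum(masked_macm > 0)))

## network overlap against a two-network reference atlas ---------------------
# synthetic reference atlas: nearest planted out-of-ROI network locus
atl_arr <- array(0L, grid$dims)
loci <- list(A = rbind(c(-6, 50, 30), c(-44, -60, 40)),
             B = rbind(c(-50, -40, 6), c(-4, -20, 48)))
dA <- apply(loci$A, 1, function(p) sqrt(rowSums(sweep(grid$mm, 2, p)^2)))
dB <- apply(loci$B, 1, function(p) sqrt(rowSums(sweep(grid$mm, 2, p)^2)))
near <- pmin(dA[, 1], dA[, 2], dB[, 1], dB[, 2])
lab <- ifelse(pmin(dA[, 1], dA[, 2]) <= pmin(dB[, 1], dB[, 2]), 1L, 2L)
lab[near > 40] <- 0L                     # background beyond the networks
atl_arr[seq_len(nrow(grid$mm))] <- lab
atlas <- brain_vol(atl_arr, grid$affine)
mask_vol <- brain_vol(array(as.numeric(masked_macm > 0), grid$dims),
                      grid$affine)
if (any(mask_vol$data != 0)) {
  ov <- network_overlap(mask_vol, atlas,
                        labels = c("1" = "network_A", "2" = "network_B"))
  write.table(ov, file.path(out, "network_overlap_high.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("network overlap of the high>low coactivation map:\n")
  print(ov)
}

## functional decoding --------------------------------------------------------
dec_high <- decode_seed(db, seed_high, annotation, q = 0.05)
dec_low <- decode_seed(db, seed_low, annotation, q = 0.05)
write.table(dec_high$forward, file.path(out, "decoding_forward_high.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dec_high$reverse, file.path(out, "decoding_reverse_high.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(dec_low$forward, file.path(out, "decoding_forward_low.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
sig_hi <- dec_high$forward$term[dec_high$forward$significant &
                                  dec_high$forward$direction > 0]
sig_lo <- dec_low$forward$term[dec_low$forward$significant &
                                 dec_low$forward$direction > 0]
top_terms <- function(tab, k = 5) {
  tab <- tab[tab$direction > 0, ]
  head(tab$term[order(tab$chisq, decreasing = TRUE)], k)
}
cat("terms surviving FDR (high / low cluster):",
    if (length(sig_hi)) paste(sig_hi, collapse = ", ") else "none", "/",
    if (length(sig_lo)) paste(sig_lo, collapse = ", ") else "none", "\n")
cat("top descriptive associations, high cluster:",
    paste(top_terms(dec_high$forward), collapse = ", "), "\n")
cat("top descriptive associations, low cluster:",
    paste(top_terms(dec_low$forward), collapse = ", "), "\n")

jsonlite::write_json(
  list(cluster_voxels_per_tail = length(ext$low),
       fc_contrast_high = sum(masked_hi > 0),
       fc_contrast_low = sum(masked_lo > 0),
       conjunction_voxels = sum(conj),
       macm_contrast_voxels = sum(masked_macm > 0),
       decoded_terms_high = sig_hi, decoded_terms_low = sig_lo),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
cat("wrote", out, "\n")
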