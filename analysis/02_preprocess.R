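#!/usr/bin/env Rscript
# Step 2 — minimal preprocessing.
#
# Spatial smoothing (5 mm FWHM Gaussian) and zero-phase high-pass temporal
# filtering (0.01 Hz cutoff). No variance normalization: the amplitude
# analysis downstream needs the raw signal scale.

suppressMessages(library(subnetica))

indir <- "results/analysis/data"
out <- "results/analysis/preproc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- read_dataset(indir)
params <- preproc_params(fwhm_mm = 5, highpass_cutoff_hz = 0.01,
                         tr_s = ds$subjects[[1]]$tr_s)
cat(sprintf("Smoothing sigma: %.3f voxels; high-pass cutoff %.3f Hz\n",
            fwhm_to_sigma(params$fwhm_mm) / ds$subjects[[1]]$voxel_mm[1],
            params$highpass_cutoff_hz))

for (sub in ds$subjects) {
  pp <- preprocess_subject(sub, params)
  img <- RNifti::asNifti(pp$data)
  img$pixdim <- c(-1, pp$voxel_mm, pp$tr_s, 0, 0, 0)
  RNifti::writeNifti(img, file.path(out, paste0(sub$id, ".nii.gz")))
}
file.copy(file.path(indir, "subjects.tsv"), file.path(out, "subjects.tsv"),
          overwrite = TRUE)
cat("Preprocessed", length(ds$subjects), "subjects into", out, "\n")
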