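#!/usr/bin/env Rscript
# Step 5 — spatio-temporal labeling of high-D subnetworks.
#
# Each D = 7 component is matched to the D = 3 reference networks by spatial
# overlap (Dice on maps thresholded at pseudo-z > 3) and by temporal
# correlation of the stage-1 series (Pearson r averaged across subjects).
# Components whose best Dice < 0.1 or best correlation < 0.4 are residual
# noise; disagreement between the two matches gives "unknown".

suppressMessages(library(subnetica))

icadir <- "results/analysis/groupica"
drdir <- "results/analysis/dualreg"
out <- "results/analysis"

mask_img <- RNifti::readNifti(file.path(icadir, "mask.nii.gz"))
d3 <- dim(mask_img)[1:3]
read_maps <- function(D) array(as.numeric(RNifti::readNifti(
  file.path(icadir, sprintf("groupica_D%d.nii.gz", D)))), c(d3, D))
read_ts <- function(D) {
  files <- sort(list.files(file.path(drdir, sprintf("timeseries_D%d", D)),
                           full.names = TRUE))
  lapply(files, function(f) as.matrix(read.delim(f)))
}

dc <- dice_matrix(read_maps(7), read_maps(3), z_thresh = 3)
tc <- temporal_corr_matrix(read_ts(7), read_ts(3))
la <- assign_labels(match_evidence(dc, tc))

write.table(la$labels, file.path(out, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Label assignment:\n")
print(la$labels)
cat("\nMembers per reference network:\n")
tab <- la$labels$label[!(la$labels$label %in% c("noise", "unknown"))]
print(table(tab))
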