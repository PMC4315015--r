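#!/usr/bin/env Rscript
# Step 6 — group comparisons.
#
# Temporal: per-component amplitude (SD of the raw stage-1 series) and
# edge-wise Fisher-z netmats over the labeled subnetworks, compared between
# groups with two-sample t-tests and permutation max-|t| FWE correction
# (amplitude: one family at low D, one family per parent at high D; netmat:
# within-network and between-network edge families). Spatial: voxelwise
# cluster-permutation tests (cluster-forming p < 0.05, max-cluster-size
# null) on the stage-2 maps, testing A > B.

suppressMessages(library(subnetica))

drdir <- "results/analysis/dualreg"
icadir <- "results/analysis/groupica"
out <- "results/analysis"
n_perm <- 1000
seed <- 55

subj <- read.delim("results/analysis/preproc/subjects.tsv")
groups <- subj$group
labels <- read.delim(file.path(out, "labels.tsv"))
keep <- !(labels$label %in% c("noise", "unknown"))
members <- labels$component[keep]
parent_of <- as.integer(labels$label[keep])

read_ts <- function(D) {
  files <- file.path(drdir, sprintf("timeseries_D%d", D),
                     paste0(subj$subject_id, ".tsv"))
  lapply(files, function(f) as.matrix(read.delim(f)))
}
ts3 <- read_ts(3); ts7 <- read_ts(7)

## Amplitude
amp3 <- t(vapply(ts3, function(m) amplitude(m), numeric(3)))
amp7 <- t(vapply(ts7, function(m) amplitude(m), numeric(7)))[, members,
                                                             drop = FALSE]
cmp3 <- compare_groups(amp3, groups, n_perm = n_perm, seed = seed)
cmp7 <- compare_groups(amp7, groups,
                       family = sprintf("parent%d", parent_of),
                       n_perm = n_perm, seed = seed + 1)
amp_tab <- rbind(data.frame(dimension = "low", cmp3),
                 data.frame(dimension = "high", cmp7))
amp_tab$significant <- amp_tab$p_fwe < 0.05
write.table(amp_tab, file.path(out, "amplitude_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Amplitude comparisons (significant after FWE):\n")
print(amp_tab[amp_tab$significant,
              c("dimension", "test", "statistic", "p_fwe")])

## Netmats over labeled high-D components
et <- edge_table(parent_of)
z <- matrix(0, length(ts7), nrow(et))
for (s in seq_along(ts7)) {
  nm <- netmat(ts7[[s]][, members, drop = FALSE])
  z[s, ] <- nm[cbind(et$i, et$j)]
}
colnames(z) <- sprintf("IC%d~IC%d", members[et$i], members[et$j])
cmpN <- compare_groups(z, groups, family = et$family, n_perm = n_perm,
                       seed = seed + 2)
cmpN$significant <- cmpN$p_fwe < 0.05
write.table(cmpN, file.path(out, "netmat_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nNetmat edges with significant group differences:\n")
print(cmpN[cmpN$significant, c("test", "family", "statistic", "p_fwe")])

## Spatial maps: cluster-permutation per labeled component
mask <- array(as.numeric(RNifti::readNifti(
  file.path(icadir, "mask.nii.gz"))) > 0.5, dim(RNifti::readNifti(
    file.path(icadir, "mask.nii.gz")))[1:3])
read_stage2 <- function(D, comp) {
  arrs <- lapply(subj$subject_id, function(id) {
    a <- as.numeric(RNifti::readNifti(
      file.path(drdir, sprintf("maps_D%d", D), paste0(id, ".nii.gz"))))
    array(a, c(dim(mask), D))[, , , comp]
  })
  array(unlist(arrs), c(dim(mask), length(arrs)))
}
rows <- list()
for (comp in members) {
  stack <- read_stage2(7, comp)
  res <- cluster_permutation_test(stack[, , , groups == "A"],
                                  stack[, , , groups == "B"],
                                  cluster_forming_p = 0.05,
                                  n_perm = n_perm, direction = "A>B",
                                  mask = mask, seed = seed + comp)
  if (nrow(res$clusters))
    rows[[length(rows) + 1]] <- data.frame(component = comp, res$clusters)
}
cl_tab <- if (length(rows)) do.call(rbind, rows) else
  data.frame(component = integer(0))
write.table(cl_tab, file.path(out, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nClusters (A > B) with FWE p < 0.05:\n")
if (nrow(cl_tab)) print(cl_tab[cl_tab$p_fwe < 0.05, ]) else cat("none\n")
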