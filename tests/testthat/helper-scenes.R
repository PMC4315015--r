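# Shared fixtures: scaled-down synthetic scenes and independent oracles used
# across the test files. Everything is generated in code at test time.

# A small two-parent scene (2 + 2 subnets) for fast ICA/labeling tests.
small_scene <- function(n_per_group = 5, n_volumes = 80, noise_sd = 1,
                        seed = 11, amplitude_ratio = 0.7,
                        coupling_delta = 0.2) {
  grid <- scene_grid(c(16, 16, 10), 3)
  blob <- function(ctr) make_subnet_map(ctr, radius_mm = 6, grid = grid,
                                        softness_mm = 2)
  specs <- list(
    network_spec(1, list(blob(c(4, 4, 4)), blob(c(4, 12, 6))),
                 parent_coupling = 0.8,
                 group_amplitude_ratio = c(amplitude_ratio, 1)),
    network_spec(2, list(blob(c(12, 4, 4)), blob(c(12, 12, 6))),
                 parent_coupling = 0.8,
                 group_coupling_delta = coupling_delta))
  list(grid = grid, specs = specs,
       dataset = generate_dataset(n_per_group = n_per_group, grid = grid,
                                  specs = specs, noise_sd = noise_sd,
                                  n_volumes = n_volumes, seed = seed))
}

# Brute-force Dice over all pairs of thresholded maps (oracle for
# dice_matrix).
dice_matrix_oracle <- function(high_arr, low_arr, z_thresh,
                               z_thresh_low = z_thresh) {
  nh <- dim(high_arr)[4]; nl <- dim(low_arr)[4]
  out <- matrix(0, nh, nl)
  for (i in seq_len(nh)) for (j in seq_len(nl))
    out[i, j] <- dice_coefficient(high_arr[, , , i] > z_thresh,
                                  low_arr[, , , j] > z_thresh_low)
  out
}

# Independent re-implementation of the labeling rule, enumerating every
# (i, j) decision explicitly (oracle for assign_labels).
assign_labels_oracle <- function(DC, TC, theta_dc = 0.1, theta_tc = 0.4,
                                 rule = "or") {
  n <- nrow(DC)
  out <- character(n)
  for (i in seq_len(n)) {
    best_dc <- -Inf; js <- NA; best_tc <- -Inf; jt <- NA
    for (j in seq_len(ncol(DC))) {
      if (DC[i, j] > best_dc) { best_dc <- DC[i, j]; js <- j }
      if (TC[i, j] > best_tc) { best_tc <- TC[i, j]; jt <- j }
    }
    noise <- if (rule == "or") (best_dc < theta_dc) || (best_tc < theta_tc)
             else (best_dc < theta_dc) && (best_tc < theta_tc)
    out[i] <- if (noise) "noise" else if (js != jt) "unknown"
              else as.character(js)
  }
  out
}

# Brute-force connected-component labeling by repeated region growing
# (oracle for label_clusters).
label_clusters_oracle <- function(binary_map, connectivity) {
  d <- dim(binary_map)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- with(offs, abs(dx) + abs(dy) + abs(dz))
  keep <- m > 0 & m <= switch(as.character(connectivity),
                              "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (v in which(binary_map)) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]; size <- size + 1L
      ijk <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- ijk + as.integer(offs[o, ])
        if (any(p < 1) || any(p > d)) next
        w <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (binary_map[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Fraction of high-D components, among those clearly matching a true subnet
# (truth Dice > 0.3), that are labeled with that subnet's true parent; plus
# the count of cross-parent errors against truth-Dice-0 parents.
labeling_vs_truth <- function(assignment, ica_high, ica_low, dataset,
                              z_thresh = 3) {
  truth <- truth_masks(dataset) + 0
  parent_of_subnet <- subnet_parents(dataset$specs)
  dct <- dice_matrix(ica_high, truth, z_thresh = z_thresh, z_thresh_low = 0.5)
  dcl <- dice_matrix(ica_low, truth, z_thresh = z_thresh, z_thresh_low = 0.5)
  # True parent of each low-D reference component: the parent its map
  # overlaps (by summed truth dice).
  low_parent <- apply(dcl, 1, function(r)
    parent_of_subnet[which.max(r)])
  lab <- assignment$labels
  n_match <- 0L; n_correct <- 0L; n_cross <- 0L
  for (i in seq_len(nrow(lab))) {
    best <- which.max(dct[i, ])
    if (dct[i, best] <= 0.3) next
    n_match <- n_match + 1L
    true_parent <- parent_of_subnet[best]
    if (lab$label[i] %in% c("noise", "unknown")) next
    got_parent <- low_parent[as.integer(lab$label[i])]
    if (got_parent == true_parent) n_correct <- n_correct + 1L
    else if (dct[i, parent_of_subnet == got_parent] == 0 ||
             max(dct[i, parent_of_subnet == got_parent]) == 0)
      n_cross <- n_cross + 1L
  }
  list(n_match = n_match, n_correct = n_correct, n_cross = n_cross,
       accuracy = if (n_match) n_correct / n_match else NA_real_)
}
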