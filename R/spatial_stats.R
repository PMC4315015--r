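# Voxelwise group comparison of subject spatial maps with nonparametric
# cluster-extent inference: one-sided t-map, cluster-forming threshold at the
# t-value whose one-sided p equals cluster_forming_p, and family-wise error
# control from the permutation null distribution of the maximum cluster size.

#' Label connected components of a binary 3D map
#'
#' @param binary_map logical 3D array.
#' @param connectivity 6, 18, or 26 (neuroimaging default 26).
#' @return list with `labels` (integer 3D array, 0 = background, clusters
#'   renumbered so label 1 is the largest) and `sizes` (data.frame `cluster`,
#'   `size`, sorted descending).
#' @export
label_clusters <- function(binary_map, connectivity = 26) {
  stopifnot(is.array(binary_map), length(dim(binary_map)) == 3L)
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  connectivity <- as.integer(connectivity)
  res <- label_components_cpp(as.logical(binary_map), dim(binary_map),
                              connectivity)
  sizes <- res$sizes
  labels <- array(res$labels, dim(binary_map))
  if (length(sizes)) {
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(length(sizes))
    remap[ord] <- seq_along(sizes)
    labels[labels > 0] <- remap[labels[labels > 0]]
    sizes <- sizes[ord]
  }
  list(labels = labels,
       sizes = data.frame(cluster = seq_along(sizes), size = sizes))
}

#' Permutation test with max-cluster-size FWE correction
#'
#' Computes the one-sided pooled-variance t-map for the requested direction,
#' thresholds it at `qt(1 - cluster_forming_p, df)` with
#' `df = n_A + n_B - 2`, finds connected clusters, and corrects each
#' cluster's size against the permutation null distribution of the maximum
#' cluster size (the observed labeling is included among the permutations).
#' When fewer distinct labelings than `n_perm` exist they are enumerated
#' exhaustively with a warning.
#'
#' @param maps_a,maps_b 4D arrays `[x, y, z, subject]` of per-subject maps
#'   for groups A and B on a shared grid.
#' @param cluster_forming_p one-sided voxelwise p defining the cluster-forming
#'   threshold (in (0, 1)).
#' @param n_perm number of permutations, observed labeling included.
#' @param direction `"A>B"` or `"B>A"`: the tested one-sided contrast.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @param mask logical 3D array; defaults to voxels with nonzero variance.
#' @param seed integer seed.
#' @return a `cluster_result`: `t_map` (3D, 0 outside mask), `clusters`
#'   (data.frame `cluster`, `size`, `peak_x/y/z`, `peak_t`, `p_fwe`),
#'   `t_thresh`, `null_max_sizes`, `n_perm`, `direction`, `seed`.
#' @export
cluster_permutation_test <- function(maps_a, maps_b, cluster_forming_p = 0.05,
                                     n_perm = 5000,
                                     direction = c("A>B", "B>A"),
                                     connectivity = 26, mask = NULL,
                                     seed = 1) {
  direction <- match.arg(direction)
  stopifnot(length(dim(maps_a)) == 4L, length(dim(maps_b)) == 4L,
            cluster_forming_p > 0, cluster_forming_p < 1)
  if (!identical(dim(maps_a)[1:3], dim(maps_b)[1:3]))
    stop("groups are on different grids")
  n_a <- dim(maps_a)[4]; n_b <- dim(maps_b)[4]
  if (n_a < 2L || n_b < 2L) stop("need >= 2 subjects per group")
  d3 <- dim(maps_a)[1:3]
  Xa <- t(matrix(maps_a, prod(d3), n_a))
  Xb <- t(matrix(maps_b, prod(d3), n_b))
  X <- rbind(Xa, Xb)
  if (is.null(mask)) {
    v <- apply(X, 2L, stats::var)
    mask <- array(v > 1e-12 & is.finite(v), d3)
  }
  Xm <- X[, as.vector(mask), drop = FALSE]
  labels <- rep(c("A", "B"), c(n_a, n_b))
  G <- perm_indicators(labels, n_perm, derive_seed(seed, "cluster-perm"))
  t_all <- perm_t_matrix(Xm, G)
  if (direction == "B>A") t_all <- -t_all
  df <- n_a + n_b - 2
  t_thresh <- stats::qt(1 - cluster_forming_p, df)
  # Embed into the full grid; voxels outside the mask can never be
  # suprathreshold.
  t_full <- matrix(-Inf, nrow(t_all), prod(d3))
  t_full[, as.vector(mask)] <- t_all
  max_sizes <- max_cluster_sizes_cpp(t_full, t_thresh, d3,
                                     as.integer(connectivity))
  t_map <- array(0, d3)
  t_map[as.vector(mask)] <- t_all[1, ]
  cl <- label_clusters(t_map > t_thresh & mask, connectivity)
  clusters <- cl$sizes
  if (nrow(clusters)) {
    clusters$p_fwe <- vapply(clusters$size,
                             function(s) mean(max_sizes >= s), 0)
    peaks <- t(vapply(seq_len(nrow(clusters)), function(k) {
      in_k <- which(cl$labels == k, arr.ind = TRUE)
      pk <- in_k[which.max(t_map[in_k]), ]
      c(pk, t_map[matrix(pk, 1)])
    }, numeric(4)))
    clusters$peak_x <- as.integer(peaks[, 1])
    clusters$peak_y <- as.integer(peaks[, 2])
    clusters$peak_z <- as.integer(peaks[, 3])
    clusters$peak_t <- peaks[, 4]
  } else {
    clusters$p_fwe <- numeric(0)
    clusters$peak_x <- integer(0); clusters$peak_y <- integer(0)
    clusters$peak_z <- integer(0); clusters$peak_t <- numeric(0)
  }
  structure(list(t_map = t_map, cluster_labels = cl$labels,
                 clusters = clusters, t_thresh = t_thresh,
                 cluster_forming_p = cluster_forming_p,
                 null_max_sizes = max_sizes, n_perm = nrow(G),
                 direction = direction, connectivity = connectivity,
                 mask = mask, seed = as.integer(seed)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %s, t_thresh = %.3f, %d clusters, %d permutations\n",
              x$direction, x$t_thresh, nrow(x$clusters), x$n_perm))
  if (nrow(x$clusters)) print(x$clusters, ...)
  invisible(x)
}
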