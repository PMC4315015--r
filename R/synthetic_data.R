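# Synthetic multi-subject BOLD generator with planted hierarchical networks.
#
# The generator emulates a resting-state acquisition: a handful of parent
# networks, each decomposed into spatially compact subnetworks whose time
# courses share a parent signal, plus white measurement noise. A group effect
# is planted as (i) reduced time-course amplitude and (ii) reduced coupling to
# the parent signal in group B, mirroring the within-network connectivity loss
# the pipeline is designed to detect.

#' Create a smooth spherical network map
#'
#' A Gaussian-tapered ball: weight 1 inside `radius_mm` of the center, decaying
#' as `exp(-0.5 * ((d - radius) / softness)^2)` outside. Used as the spatial
#' footprint of one subnetwork.
#'
#' @param center voxel coordinate (1-based, length 3) of the blob center.
#' @param radius_mm radius of the flat core, in mm.
#' @param grid a [scene_grid()].
#' @param softness_mm Gaussian taper scale outside the core, in mm.
#' @return 3D nonnegative array with maximum 1 at `center`.
#' @export
make_subnet_map <- function(center, radius_mm, grid, softness_mm = 2) {
  stopifnot(inherits(grid, "scene_grid"), radius_mm > 0, softness_mm > 0)
  center <- as.numeric(center)
  if (length(center) != 3L)
    stop("`center` must be a length-3 voxel coordinate")
  if (any(center < 1) || any(center > grid$dim))
    stop("`center` lies outside the grid (dim ",
         paste(grid$dim, collapse = "x"), ")")
  ax <- lapply(1:3, function(k)
    (seq_len(grid$dim[k]) - center[k]) * grid$voxel_mm[k])
  d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  d <- sqrt(d2)
  w <- ifelse(d <= radius_mm, 1,
              exp(-0.5 * ((d - radius_mm) / softness_mm)^2))
  array(w, grid$dim)
}

#' Specify one parent network and its subnetworks
#'
#' @param parent_id integer id of the parent network.
#' @param subnet_maps list of 3D nonnegative weight volumes, one per subnet.
#' @param parent_coupling fraction in `[0, 1]` of each subnet time course shared
#'   with the parent signal (scalar or per-subnet). The correlation between two
#'   subnets of one parent is the product of their effective couplings.
#' @param group_amplitude_ratio multiplicative factor (> 0) applied to group B
#'   time courses (scalar or per-subnet).
#' @param group_coupling_delta reduction of `parent_coupling` in group B
#'   (scalar or per-subnet; effective coupling is floored at 0).
#' @return a `network_spec` object.
#' @export
network_spec <- function(parent_id, subnet_maps, parent_coupling = 0.8,
                         group_amplitude_ratio = 1, group_coupling_delta = 0) {
  if (!is.list(subnet_maps) || length(subnet_maps) == 0L)
    stop("`subnet_maps` must be a non-empty list of 3D arrays")
  n <- length(subnet_maps)
  parent_coupling <- rep_len(as.numeric(parent_coupling), n)
  group_amplitude_ratio <- rep_len(as.numeric(group_amplitude_ratio), n)
  group_coupling_delta <- rep_len(as.numeric(group_coupling_delta), n)
  vals <- c(parent_coupling, group_amplitude_ratio, group_coupling_delta)
  if (any(!is.finite(vals)))
    stop("network_spec parameters must be finite")
  if (any(parent_coupling < 0 | parent_coupling > 1))
    stop("`parent_coupling` must lie in [0, 1]")
  if (any(group_amplitude_ratio <= 0))
    stop("`group_amplitude_ratio` must be > 0")
  for (m in subnet_maps) {
    if (!is.array(m) || length(dim(m)) != 3L)
      stop("each subnet map must be a 3D array")
    if (any(!is.finite(m)) || any(m < 0))
      stop("subnet maps must be finite and nonnegative")
    if (!any(m > 0.5))
      stop("each subnet map needs at least one suprathreshold (> 0.5) voxel")
  }
  structure(list(parent_id = as.integer(parent_id),
                 subnet_ids = seq_len(n),
                 subnet_maps = subnet_maps,
                 parent_coupling = parent_coupling,
                 group_amplitude_ratio = group_amplitude_ratio,
                 group_coupling_delta = group_coupling_delta),
            class = "network_spec")
}

# Unit-variance stationary AR(1) series.
ar1_series <- function(n, phi) {
  x1 <- stats::rnorm(1)
  if (n == 1L) return(x1)
  e <- stats::rnorm(n - 1L, sd = sqrt(1 - phi^2))
  c(x1, stats::filter(e, phi, method = "recursive", init = x1))
}

#' Simulate subnetwork time courses for one subject
#'
#' Each subnet course is `c * parent + sqrt(1 - c^2) * unique`, where parent
#' and unique signals are unit-variance AR(1) processes and `c` is the
#' effective parent coupling (reduced by `group_coupling_delta` in group B).
#' Group B courses are then scaled by `group_amplitude_ratio`. Two subnets of
#' one parent therefore have expected correlation equal to the product of
#' their effective couplings.
#'
#' @param n_volumes number of time points (>= 10).
#' @param specs list of [network_spec()] objects.
#' @param group `"A"` or `"B"`.
#' @param ar_coef AR(1) coefficient of all latent signals (|ar_coef| < 1).
#' @param seed integer seed.
#' @return matrix (volumes x total subnets), columns ordered by spec then
#'   subnet.
#' @export
make_timecourses <- function(n_volumes, specs, group = c("A", "B"),
                             ar_coef = 0.3, seed = 1) {
  group <- match.arg(group)
  if (inherits(specs, "network_spec")) specs <- list(specs)
  stopifnot(n_volumes >= 10, abs(ar_coef) < 1)
  set.seed(seed)
  cols <- list()
  for (spec in specs) {
    parent <- ar1_series(n_volumes, ar_coef)
    for (k in seq_along(spec$subnet_ids)) {
      u <- ar1_series(n_volumes, ar_coef)
      cc <- spec$parent_coupling[k]
      if (group == "B")
        cc <- max(cc - spec$group_coupling_delta[k], 0)
      x <- cc * parent + sqrt(1 - cc^2) * u
      if (group == "B") x <- x * spec$group_amplitude_ratio[k]
      cols[[length(cols) + 1L]] <- x
    }
  }
  tc <- do.call(cbind, cols)
  colnames(tc) <- subnet_names(specs)
  tc
}

subnet_names <- function(specs) {
  unlist(lapply(specs, function(s)
    sprintf("P%d.%d", s$parent_id, s$subnet_ids)))
}

#' Parent network id of each subnet, in generation order
#' @param specs list of [network_spec()] objects.
#' @return integer vector, one entry per subnet.
#' @export
subnet_parents <- function(specs) {
  if (inherits(specs, "network_spec")) specs <- list(specs)
  unlist(lapply(specs, function(s) rep(s$parent_id, length(s$subnet_ids))))
}

#' Generate a multi-subject synthetic dataset
#'
#' Each subject's 4D data is the sum over subnets of (spatial map x time
#' course) plus i.i.d. Gaussian noise. Group labels alternate A/B blocks of
#' `n_per_group`; group B gets the planted amplitude and coupling effects
#' declared in the specs. Fully reproducible from `seed`.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param grid a [scene_grid()].
#' @param specs list of [network_spec()] objects.
#' @param noise_sd standard deviation of the additive white noise.
#' @param tr_s repetition time in seconds.
#' @param n_volumes time points per subject.
#' @param seed integer master seed.
#' @param ar_coef AR(1) coefficient of the latent signals.
#' @param allow_overlap allow spatial overlap between different parents'
#'   maps (off by default; overlapping parents are rejected otherwise).
#' @return a `synthetic_dataset` with `subjects`, `truth_maps` (4D stack),
#'   `truth_timecourses` (list per subject), `group_labels`, `tr_s`, `seed`,
#'   `specs`, `grid`.
#' @export
generate_dataset <- function(n_per_group = 20, grid, specs, noise_sd = 1,
                             tr_s = 2.5, n_volumes = 160, seed = 1,
                             ar_coef = 0.3, allow_overlap = FALSE) {
  stopifnot(n_per_group >= 2, inherits(grid, "scene_grid"))
  if (inherits(specs, "network_spec")) specs <- list(specs)
  check_parent_overlap(specs, allow_overlap)
  map_mat <- do.call(cbind, unlist(lapply(specs, function(s)
    lapply(s$subnet_maps, as.vector)), recursive = FALSE))
  colnames(map_mat) <- subnet_names(specs)
  n_sub <- 2L * n_per_group
  groups <- rep(c("A", "B"), each = n_per_group)
  ids <- sprintf("sub-%02d", seq_len(n_sub))
  subjects <- vector("list", n_sub)
  truth_tc <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    tc <- make_timecourses(n_volumes, specs, group = groups[s],
                           ar_coef = ar_coef,
                           seed = derive_seed(seed, paste0("tc-", s)))
    set.seed(derive_seed(seed, paste0("noise-", s)))
    vol <- map_mat %*% t(tc)
    if (noise_sd > 0)
      vol <- vol + stats::rnorm(length(vol), sd = noise_sd)
    subjects[[s]] <- subject_bold(array(vol, c(grid$dim, n_volumes)),
                                  voxel_mm = grid$voxel_mm, tr_s = tr_s,
                                  id = ids[s], group = groups[s])
    truth_tc[[s]] <- tc
  }
  names(truth_tc) <- ids
  structure(list(subjects = subjects,
                 truth_maps = array(map_mat, c(grid$dim, ncol(map_mat))),
                 truth_timecourses = truth_tc,
                 group_labels = stats::setNames(groups, ids),
                 tr_s = tr_s, n_volumes = as.integer(n_volumes),
                 seed = as.integer(seed), specs = specs, grid = grid),
            class = "synthetic_dataset")
}

check_parent_overlap <- function(specs, allow_overlap, thresh = 0.1) {
  if (allow_overlap || length(specs) < 2L) return(invisible(TRUE))
  footprints <- lapply(specs, function(s) {
    f <- Reduce(pmax, s$subnet_maps)
    f > thresh
  })
  for (i in seq_along(specs)[-1]) for (j in seq_len(i - 1L)) {
    if (any(footprints[[i]] & footprints[[j]]))
      stop("maps of parents ", specs[[j]]$parent_id, " and ",
           specs[[i]]$parent_id, " overlap; pass allow_overlap = TRUE ",
           "to permit this")
  }
  invisible(TRUE)
}

#' Binary ground-truth masks of the planted subnetworks
#' @param dataset a `synthetic_dataset`.
#' @param thresh weight threshold defining membership.
#' @return logical 4D array `[x, y, z, subnet]`.
#' @export
truth_masks <- function(dataset, thresh = 0.5) {
  dataset$truth_maps > thresh
}

#' The default synthetic scene
#'
#' Three parent networks with (2, 3, 2) subnetworks on a 24 x 24 x 16 grid of
#' 3 mm voxels: a desk-scale analog of a posterior DMN split in two, an
#' anterior DMN split in three, and a sensory-motor network split in two.
#' Group B carries reduced amplitude on subnets P1.1 and P2.2 (ratio 0.7) and
#' reduced parent coupling (delta 0.2) on P2.2 and both P3 subnets, so both
#' affected and null subnets/edges exist downstream.
#'
#' @param n_per_group subjects per group.
#' @param n_volumes time points per subject.
#' @param tr_s repetition time, seconds.
#' @param noise_sd additive noise SD.
#' @param seed master seed.
#' @param amplitude_ratio planted group-B amplitude ratio on the affected
#'   subnets.
#' @param coupling_delta planted group-B coupling reduction on the affected
#'   subnets.
#' @return list with `grid`, `specs`, and a ready [generate_dataset()] call's
#'   arguments baked in under `dataset` (lazily generated when `generate` is
#'   TRUE).
#' @param generate if TRUE (default) also generate the dataset.
#' @export
default_scene <- function(n_per_group = 20, n_volumes = 160, tr_s = 2.5,
                          noise_sd = 1, seed = 1, amplitude_ratio = 0.7,
                          coupling_delta = 0.2, generate = TRUE) {
  grid <- scene_grid(c(24, 24, 16), 3)
  blob <- function(ctr) make_subnet_map(ctr, radius_mm = 6, grid = grid,
                                        softness_mm = 2)
  specs <- list(
    network_spec(1,
                 list(blob(c(6, 6, 5)), blob(c(6, 6, 12))),
                 parent_coupling = 0.8,
                 group_amplitude_ratio = c(amplitude_ratio, 1),
                 group_coupling_delta = 0),
    network_spec(2,
                 list(blob(c(6, 18, 5)), blob(c(6, 18, 12)),
                      blob(c(12, 18, 8))),
                 parent_coupling = 0.8,
                 group_amplitude_ratio = c(1, amplitude_ratio, 1),
                 group_coupling_delta = c(0, coupling_delta, 0)),
    network_spec(3,
                 list(blob(c(18, 12, 5)), blob(c(18, 12, 12))),
                 parent_coupling = 0.8,
                 group_amplitude_ratio = 1,
                 group_coupling_delta = coupling_delta))
  out <- list(grid = grid, specs = specs,
              affected_amplitude = c(1L, 4L),
              affected_coupling = c(4L, 6L, 7L),
              n_parents = 3L, n_subnets = 7L)
  if (generate)
    out$dataset <- generate_dataset(n_per_group = n_per_group, grid = grid,
                                    specs = specs, noise_sd = noise_sd,
                                    tr_s = tr_s, n_volumes = n_volumes,
                                    seed = seed)
  out
}

#' Write a synthetic dataset to disk
#'
#' One gzipped NIfTI per subject, a `subjects.tsv` group table, the ground
#' truth map stack as NIfTI, and per-subject ground-truth time-course TSVs.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in dataset$subjects)
    write_nifti4d(sub$data, sub$voxel_mm, sub$tr_s,
                  file.path(dir, paste0(sub$id, ".nii.gz")))
  utils::write.table(
    data.frame(subject_id = names(dataset$group_labels),
               group = unname(dataset$group_labels)),
    file.path(dir, "subjects.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_nifti4d(dataset$truth_maps, dataset$grid$voxel_mm, 1,
                file.path(dir, "truth_maps.nii.gz"))
  tdir <- file.path(dir, "truth_timecourses")
  dir.create(tdir, showWarnings = FALSE)
  for (id in names(dataset$truth_timecourses))
    utils::write.table(dataset$truth_timecourses[[id]],
                       file.path(tdir, paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()] (or any per-subject NIfTI
#' directory with a `subjects.tsv` table)
#'
#' @param dir directory containing `sub-*.nii.gz` and `subjects.tsv`.
#' @param tr_s repetition time override; taken from the NIfTI header when NULL.
#' @return list of `subject_bold` plus `group_labels`.
#' @export
read_dataset <- function(dir, tr_s = NULL) {
  tab <- utils::read.delim(file.path(dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)
  subjects <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    img <- RNifti::readNifti(file.path(dir, paste0(tab$subject_id[i],
                                                   ".nii.gz")))
    pd <- RNifti::pixdim(img)
    subjects[[i]] <- subject_bold(
      array(as.numeric(img), dim(img)),
      voxel_mm = pd[1:3],
      tr_s = if (is.null(tr_s)) pd[4] else tr_s,
      id = tab$subject_id[i], group = tab$group[i])
  }
  list(subjects = subjects,
       group_labels = stats::setNames(tab$group, tab$subject_id))
}

write_nifti4d <- function(arr, voxel_mm, tr_s, path) {
  img <- RNifti::asNifti(arr)
  img$pixdim <- c(-1, voxel_mm, tr_s, 0, 0, 0)
  RNifti::writeNifti(img, path)
  invisible(path)
}
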