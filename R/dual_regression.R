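# Dual regression: stage 1 regresses each volume onto the group spatial maps
# to give subject-specific time series; stage 2 regresses each voxel's time
# series onto those courses to give subject-specific spatial maps.

#' Dual-regression stage 1: subject-specific time series
#'
#' For every volume, the voxel vector is regressed simultaneously onto all D
#' demeaned group maps; the coefficient series are returned on the raw data
#' scale (no normalization — downstream amplitude analysis is the SD of these
#' series).
#'
#' @param subject a `subject_bold`.
#' @param group_maps a `group_ica` result (or anything [maps_to_array()]
#'   accepts together with `mask`).
#' @param mask logical 3D array; defaults to the group-ICA mask.
#' @return matrix (volumes x D).
#' @export
stage1_timeseries <- function(subject, group_maps, mask = NULL) {
  mm <- as_map_matrix(group_maps, mask)
  if (!identical(dim(subject$data)[1:3], mm$dim))
    stop("subject ", subject$id, " and group maps are on different grids")
  G <- t(mm$maps)                       # voxels x D
  G <- sweep(G, 2L, colMeans(G))
  qrG <- qr(G)
  if (qrG$rank < ncol(G)) {
    cc <- stats::cor(G)
    bad <- which(abs(cc) > 0.999 & upper.tri(cc), arr.ind = TRUE)
    stop("group map matrix is rank deficient; near-collinear pairs: ",
         paste(apply(bad, 1, paste, collapse = "~"), collapse = ", "))
  }
  Y <- subject_matrix(subject, mm$mask) # volumes x voxels
  ts <- t(qr.coef(qrG, t(Y)))
  colnames(ts) <- rownames(mm$maps)
  ts
}

#' Dual-regression stage 2: subject-specific spatial maps
#'
#' Per voxel, the time series is regressed simultaneously onto all D subject
#' time courses. With `des_norm = TRUE` (FSL's recommended setting) the design
#' columns are scaled to unit variance first, so component amplitude is
#' absorbed into the maps.
#'
#' @param subject a `subject_bold`.
#' @param timeseries matrix (volumes x D) from [stage1_timeseries()].
#' @param mask logical 3D array of voxels to fit.
#' @param des_norm scale design columns to unit variance.
#' @return a `map_stack`: `maps` (D x masked voxels, regression coefficients),
#'   `mask`, `dim`, `voxel_mm`.
#' @export
stage2_maps <- function(subject, timeseries, mask, des_norm = TRUE) {
  if (nrow(timeseries) != dim(subject$data)[4])
    stop("timeseries rows must equal the subject's volume count")
  A <- sweep(timeseries, 2L, colMeans(timeseries))
  sds <- sqrt(colMeans(A^2) * nrow(A) / (nrow(A) - 1))
  if (any(sds < 1e-12))
    stop("zero-variance time course(s): ",
         paste(which(sds < 1e-12), collapse = ", "))
  if (des_norm) A <- sweep(A, 2L, sds, "/")
  Y <- subject_matrix(subject, mask)
  B <- qr.coef(qr(A), Y)                # D x voxels
  rownames(B) <- colnames(timeseries)
  structure(list(maps = B, mask = mask, dim = dim(subject$data)[1:3],
                 voxel_mm = subject$voxel_mm, des_norm = des_norm),
            class = "map_stack")
}

#' Run both dual-regression stages for a list of subjects
#'
#' @param subjects list of `subject_bold`.
#' @param group_maps a `group_ica` result.
#' @param des_norm stage-2 design normalization (stage-1 series are always
#'   stored raw).
#' @return a `dual_regression` object with per-subject `timeseries` and
#'   `maps`, plus `subject_ids` and `groups`.
#' @export
dual_regression <- function(subjects, group_maps, des_norm = TRUE) {
  ts <- lapply(subjects, stage1_timeseries, group_maps = group_maps)
  maps <- mapply(function(sub, t1) stage2_maps(sub, t1, group_maps$mask,
                                               des_norm = des_norm),
                 subjects, ts, SIMPLIFY = FALSE)
  ids <- vapply(subjects, `[[`, "", "id")
  names(ts) <- ids; names(maps) <- ids
  structure(list(timeseries = ts, maps = maps, subject_ids = ids,
                 groups = vapply(subjects, `[[`, "", "group"),
                 des_norm = des_norm, D = group_maps$D),
            class = "dual_regression")
}
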