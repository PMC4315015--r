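# Automatic spatio-temporal labeling of high-dimensional components against
# low-dimensional reference networks: spatial evidence is the Dice overlap of
# thresholded maps, temporal evidence the across-subject mean Pearson
# correlation of the subject-specific time series. A component is labeled with
# reference network j only when both argmaxes agree and clear their
# thresholds (defaults 0.1 for Dice, 0.4 for temporal correlation); it is
# residual noise when the evidence maxima fall below threshold, and unknown
# when the spatial and temporal matches disagree.

#' Dice coefficient between two binary masks
#'
#' `2 |A n B| / (|A| + |B|)`; returns 0 when both masks are empty (documented
#' convention).
#'
#' @param mask_a,mask_b logical arrays on the same grid.
#' @return a number in `[0, 1]`.
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks are on different grids")
  na <- sum(mask_a); nb <- sum(mask_b)
  if (na + nb == 0L) return(0)
  2 * sum(mask_a & mask_b) / (na + nb)
}

#' All-pairs Dice matrix between two map stacks
#'
#' Each z-scaled map is binarized at `value > z_thresh` (positive tail, after
#' sign fixing), then every (high, low) pair's Dice coefficient is computed.
#' A map with no suprathreshold voxel yields a zero row/column and a warning.
#'
#' @param high_maps,low_maps `group_ica` results, `map_stack`s, or 4D arrays
#'   on a shared grid.
#' @param z_thresh binarization threshold (> 0), in pseudo-z units.
#' @param z_thresh_low threshold for the low stack when its scale differs
#'   (e.g. ground-truth weight maps); defaults to `z_thresh`.
#' @return matrix (high components x low components) of Dice coefficients.
#' @export
dice_matrix <- function(high_maps, low_maps, z_thresh = 3,
                        z_thresh_low = z_thresh) {
  stopifnot(z_thresh > 0, z_thresh_low > 0)
  hi <- as_map_matrix(high_maps)
  lo <- as_map_matrix(low_maps)
  if (!identical(hi$dim, lo$dim))
    stop("map stacks are on different grids")
  # Compare over the union of coverage: embed both into full-grid masks.
  hb <- expand_masks(hi, z_thresh)
  lb <- expand_masks(lo, z_thresh_low)
  empty <- c(sprintf("high %d", which(colSums(hb) == 0)),
             sprintf("low %d", which(colSums(lb) == 0)))
  if (length(empty))
    warning("map(s) with no suprathreshold voxel: ",
            paste(empty, collapse = ", "))
  inter <- crossprod(hb, lb)                    # |A n B|
  sizes <- outer(colSums(hb), colSums(lb), `+`) # |A| + |B|
  dc <- ifelse(sizes == 0, 0, 2 * inter / sizes)
  dimnames(dc) <- list(rownames(hi$maps), rownames(lo$maps))
  dc
}

expand_masks <- function(mm, z_thresh) {
  out <- matrix(0, prod(mm$dim), nrow(mm$maps))
  out[as.vector(mm$mask), ] <- t(mm$maps > z_thresh)
  out
}

#' Across-subject mean temporal correlation matrix
#'
#' Per subject, the Pearson correlation between every high-D series i and
#' low-D series j; entries are averaged arithmetically across subjects
#' (a Fisher-z mean is available via `fisher_mean`). Subjects contributing a
#' zero-variance series are excluded from the affected entries with a
#' warning; if every subject is excluded for some entry, that is an error.
#'
#' @param high_ts,low_ts lists (one element per subject) of (volumes x
#'   components) matrices; same subjects, same volume count within subject.
#' @param fisher_mean average correlations on the Fisher-z scale instead of
#'   the arithmetic mean of r.
#' @return matrix (high components x low components) of mean correlations.
#' @export
temporal_corr_matrix <- function(high_ts, low_ts, fisher_mean = FALSE) {
  stopifnot(length(high_ts) == length(low_ts), length(high_ts) >= 1L)
  acc <- NULL; cnt <- NULL; excluded <- FALSE
  for (s in seq_along(high_ts)) {
    h <- high_ts[[s]]; l <- low_ts[[s]]
    if (nrow(h) != nrow(l))
      stop("subject ", s, ": volume counts differ between series sets")
    sd_h <- apply(h, 2L, stats::sd); sd_l <- apply(l, 2L, stats::sd)
    r <- matrix(NA_real_, ncol(h), ncol(l))
    ok_h <- sd_h > 0; ok_l <- sd_l > 0
    if (any(ok_h) && any(ok_l))
      r[ok_h, ok_l] <- stats::cor(h[, ok_h, drop = FALSE],
                                  l[, ok_l, drop = FALSE])
    if (any(!ok_h) || any(!ok_l)) excluded <- TRUE
    v <- if (fisher_mean) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)) else r
    ok <- !is.na(v)
    if (is.null(acc)) {
      acc <- ifelse(ok, v, 0); cnt <- ok + 0
    } else {
      acc <- acc + ifelse(ok, v, 0); cnt <- cnt + ok
    }
  }
  if (excluded)
    warning("zero-variance series: some subjects excluded from the average")
  if (any(cnt == 0))
    stop("all subjects excluded for ", sum(cnt == 0), " (i, j) entr",
         if (sum(cnt == 0) == 1) "y" else "ies")
  tc <- acc / cnt
  if (fisher_mean) tc <- tanh(tc)
  dimnames(tc) <- list(colnames(high_ts[[1]]), colnames(low_ts[[1]]))
  tc
}

#' Bundle matching evidence
#'
#' @param DC Dice matrix (high x low), values in `[0, 1]`.
#' @param TC temporal-correlation matrix (high x low), values in `[-1, 1]`.
#' @param theta_dc Dice threshold (default 0.1).
#' @param theta_tc temporal-correlation threshold (default 0.4).
#' @param z_thresh pseudo-z used to binarize maps for `DC` (metadata).
#' @return a `match_evidence` object.
#' @export
match_evidence <- function(DC, TC, theta_dc = 0.1, theta_tc = 0.4,
                           z_thresh = 3) {
  stopifnot(is.matrix(DC), is.matrix(TC))
  if (!all(dim(DC) == dim(TC)))
    stop("DC and TC must have the same shape")
  if (length(DC) == 0L) stop("empty evidence matrices")
  stopifnot(all(DC >= 0 & DC <= 1), all(TC >= -1 & TC <= 1))
  structure(list(DC = DC, TC = TC, theta_dc = theta_dc, theta_tc = theta_tc,
                 z_thresh = z_thresh),
            class = "match_evidence")
}

#' Assign each high-dimensional component a label
#'
#' For each high-D component i let `j_s = argmax_j DC[i, j]` and
#' `j_t = argmax_j TC[i, j]` (ties broken toward the lowest j, with a
#' message). Under the default `"or"` noise rule the component is residual
#' noise when `max DC < theta_dc` OR `max TC < theta_tc`; under `"and"`, only
#' when both maxima are subthreshold. Otherwise it is labeled `j_s` when the
#' two argmaxes agree and unknown when they disagree.
#'
#' @param evidence a [match_evidence()].
#' @param noise_rule `"or"` (stricter, default) or `"and"`.
#' @return a `label_assignment`: data.frame `labels` with columns `component`,
#'   `label` (low-D index as character, or `"noise"`/`"unknown"`), `max_dc`,
#'   `max_tc`, plus the `evidence`.
#' @export
assign_labels <- function(evidence, noise_rule = c("or", "and")) {
  stopifnot(inherits(evidence, "match_evidence"))
  noise_rule <- match.arg(noise_rule)
  DC <- evidence$DC; TC <- evidence$TC
  n <- nrow(DC)
  lab <- character(n); mdc <- numeric(n); mtc <- numeric(n)
  for (i in seq_len(n)) {
    js <- which.max(DC[i, ]); jt <- which.max(TC[i, ])
    if (sum(DC[i, ] == DC[i, js]) > 1L || sum(TC[i, ] == TC[i, jt]) > 1L)
      message("component ", i, ": tied evidence, choosing lowest index")
    mdc[i] <- DC[i, js]; mtc[i] <- TC[i, jt]
    below_dc <- mdc[i] < evidence$theta_dc
    below_tc <- mtc[i] < evidence$theta_tc
    noise <- if (noise_rule == "or") below_dc || below_tc
             else below_dc && below_tc
    lab[i] <- if (noise) "noise"
              else if (js != jt) "unknown"
              else as.character(js)
  }
  structure(list(labels = data.frame(component = seq_len(n), label = lab,
                                     max_dc = mdc, max_tc = mtc),
                 evidence = evidence, noise_rule = noise_rule),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  tab <- table(x$labels$label)
  cat("<label_assignment> ", nrow(x$labels), " components: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
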