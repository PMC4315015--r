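# Temporal-concatenation group spatial ICA: PCA whitening of the stacked
# (time x voxel) data followed by fixed-point ICA with a logcosh contrast and
# symmetric decorrelation, maximizing spatial non-Gaussianity.

#' Temporally concatenate subjects into one data matrix
#'
#' Stacks each subject's (volumes x voxels) matrix in subject order after
#' demeaning every voxel time series within subject (and optionally variance
#' normalizing it). The default mask keeps voxels with nonzero variance in the
#' concatenated data.
#'
#' @param subjects list of `subject_bold` on a common grid.
#' @param mask logical 3D array; NULL for the nonzero-variance mask.
#' @param variance_normalize divide each within-subject voxel series by its SD.
#' @return a `concat_data` list: `x` (sum-of-volumes x masked voxels), `mask`,
#'   `dim`, `voxel_mm`, `subject_ids`, `rows_per_subject`.
#' @export
concatenate_subjects <- function(subjects, mask = NULL,
                                 variance_normalize = FALSE) {
  stopifnot(length(subjects) >= 1L)
  d0 <- dim(subjects[[1]]$data)[1:3]
  for (sub in subjects)
    if (!identical(dim(sub$data)[1:3], d0))
      stop("subject ", sub$id, " is not on the shared grid (",
           paste(dim(sub$data)[1:3], collapse = "x"), " vs ",
           paste(d0, collapse = "x"), ")")
  if (is.null(mask)) {
    ssq <- 0; s1 <- 0; n_tot <- 0L
    for (sub in subjects) {
      d <- dim(sub$data)
      m <- matrix(sub$data, nrow = prod(d[1:3]))
      mu <- rowMeans(m)
      ssq <- ssq + rowSums(m^2) - d[4] * mu^2
      n_tot <- n_tot + d[4]
    }
    mask <- array(ssq / n_tot > 1e-12, d0)
  }
  if (!any(mask)) stop("mask is empty")
  blocks <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    m <- subject_matrix(subjects[[i]], mask)
    m <- sweep(m, 2L, colMeans(m))
    if (variance_normalize) {
      sds <- sqrt(colMeans(m^2))
      sds[sds < 1e-12] <- 1
      m <- sweep(m, 2L, sds, "/")
    }
    blocks[[i]] <- m
  }
  structure(list(x = do.call(rbind, blocks), mask = mask, dim = d0,
                 voxel_mm = subjects[[1]]$voxel_mm,
                 subject_ids = vapply(subjects, `[[`, "", "id"),
                 rows_per_subject = vapply(subjects,
                                           function(s) dim(s$data)[4], 0L),
                 variance_normalized = variance_normalize,
                 cache = new.env(parent = emptyenv())),
            class = "concat_data")
}

# Numerically stable log(cosh(x)).
logcosh <- function(x) abs(x) + log1p(exp(-2 * abs(x))) - log(2)

# Expected value of log cosh of a standard normal (negentropy reference).
logcosh_ev <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- stats::integrate(function(x) logcosh(x) * stats::dnorm(x),
                               -Inf, Inf)$value
    val
  }
})

# Fixed-point ICA with logcosh contrast and symmetric decorrelation on
# whitened spatial data Z (D x V). Returns the best of n_restarts by the
# summed negentropy proxy.
fast_ica_symm <- function(Z, n_restarts = 3, tol = 1e-6, max_iter = 1000,
                          seed = 1) {
  D <- nrow(Z); V <- ncol(Z)
  set.seed(seed)
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), D) %*%
      t(e$vectors) %*% W
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- sym_decorrelate(matrix(stats::rnorm(D * D), D, D))
    converged <- FALSE; it <- 0L; delta <- NA_real_
    while (it < max_iter) {
      it <- it + 1L
      S <- W %*% Z
      G <- tanh(S)
      W_new <- (G %*% t(Z)) / V - diag(rowMeans(1 - G^2), D) %*% W
      W_new <- sym_decorrelate(W_new)
      delta <- max(abs(abs(rowSums(W_new * W)) - 1))
      W <- W_new
      if (delta < tol) { converged <- TRUE; break }
    }
    S <- W %*% Z
    neg <- sum((rowMeans(logcosh(S)) - logcosh_ev())^2)
    if (is.null(best) || (converged && !best$converged) ||
        (converged == best$converged && neg > best$negentropy))
      best <- list(W = W, negentropy = neg, converged = converged,
                   iters = it, delta = delta)
  }
  best
}

#' Run group spatial ICA at a given model order
#'
#' PCA-reduces the concatenated data to `D` dimensions, whitens, and runs
#' fixed-point ICA (logcosh contrast, symmetric decorrelation, best of
#' `n_restarts` by the negentropy objective). Maps are z-scored over the mask
#' and sign-fixed to positive skewness; the mixing matrix is the least-squares
#' projection of the data onto the maps.
#'
#' @param data a `concat_data` from [concatenate_subjects()].
#' @param D model order (number of components, >= 2 and <= min(rows, voxels)).
#' @param seed integer seed (ICA restarts).
#' @param n_restarts random restarts; the best converged run wins.
#' @param tol fixed-point convergence tolerance.
#' @param max_iter maximum fixed-point iterations per restart.
#' @return a `group_ica` object: `maps` (D x masked voxels, z-scaled), `mask`,
#'   `dim`, `voxel_mm`, `mixing` (total volumes x D), `pca_explained`, `D`,
#'   `seed`, `converged`, `iters`.
#' @export
run_group_ica <- function(data, D, seed = 1, n_restarts = 3, tol = 1e-6,
                          max_iter = 1000) {
  stopifnot(inherits(data, "concat_data"))
  X <- data$x
  D <- as.integer(D)
  if (D < 1L || D > min(dim(X)))
    stop("model order D must lie in [1, ", min(dim(X)), "]")
  X <- X - rowMeans(X)
  V <- ncol(X)
  # The PCA of the concatenated data does not depend on D; cache the top
  # eigenpairs so several model orders on one dataset share the heavy step.
  cache <- if (!is.null(data$cache)) data$cache else
    new.env(parent = emptyenv())
  keep <- min(nrow(X), max(D, 128L))
  eig <- get0("eig", envir = cache, inherits = FALSE)
  if (is.null(eig) || ncol(eig$vectors) < min(keep, D)) {
    C <- tcrossprod(X) / (V - 1)
    full <- eigen(C, symmetric = TRUE)
    eig <- list(values = pmax(full$values, 0),
                vectors = full$vectors[, seq_len(keep), drop = FALSE])
    assign("eig", eig, envir = cache)
  }
  lam <- eig$values
  E <- eig$vectors[, seq_len(D), drop = FALSE]
  lam_d <- lam[seq_len(D)]
  if (any(lam_d <= 1e-12))
    stop("data rank below requested model order D = ", D)
  Z <- diag(1 / sqrt(lam_d), D) %*% crossprod(E, X)   # D x V whitened
  if (D == 1L) {
    ica <- list(W = matrix(1, 1, 1), negentropy = NA_real_, converged = TRUE,
                iters = 0L, delta = 0)
  } else {
    ica <- fast_ica_symm(Z, n_restarts = n_restarts, tol = tol,
                         max_iter = max_iter,
                         seed = derive_seed(seed, "ica-restarts"))
    if (!ica$converged)
      stop("ICA failed to converge after ", n_restarts, " restarts (last ",
           "delta = ", signif(ica$delta, 3), ", tol = ", tol, ", max_iter = ",
           max_iter, ")")
  }
  S <- ica$W %*% Z
  S <- (S - rowMeans(S)) / sqrt(rowMeans(S^2) - rowMeans(S)^2)
  mixing <- X %*% t(S) %*% solve(tcrossprod(S))
  res <- structure(list(maps = S, mask = data$mask, dim = data$dim,
                        voxel_mm = data$voxel_mm, mixing = mixing,
                        pca_explained = lam / sum(lam), D = D,
                        seed = as.integer(seed), converged = ica$converged,
                        iters = ica$iters,
                        rows_per_subject = data$rows_per_subject,
                        subject_ids = data$subject_ids),
                   class = "group_ica")
  fix_signs(res)
}

#' @export
print.group_ica <- function(x, ...) {
  cat(sprintf("<group_ica> D = %d over %d masked voxels, %d rows; top-D variance %.1f%%\n",
              x$D, ncol(x$maps), nrow(x$mixing),
              100 * sum(x$pca_explained[seq_len(x$D)])))
  invisible(x)
}

#' Fix component signs to positive spatial skewness
#'
#' Negates every map whose voxel-value skewness is negative, together with its
#' mixing column, leaving the reconstruction unchanged. Zero skewness is left
#' untouched (tie rule).
#'
#' @param result a `group_ica` object.
#' @return the sign-fixed `group_ica`.
#' @export
fix_signs <- function(result) {
  stopifnot(inherits(result, "group_ica"))
  S <- result$maps
  mu <- rowMeans(S)
  sdv <- sqrt(rowMeans(S^2) - mu^2)
  skew <- rowMeans((S - mu)^3) / sdv^3
  flip <- which(skew < 0)
  if (length(flip)) {
    result$maps[flip, ] <- -result$maps[flip, ]
    result$mixing[, flip] <- -result$mixing[, flip]
  }
  result
}
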