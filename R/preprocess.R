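# Minimal preprocessing: isotropic Gaussian spatial smoothing and zero-phase
# Butterworth high-pass temporal filtering. No variance normalization happens
# here: downstream amplitude analysis needs the raw scale.

#' Convert a Gaussian FWHM to its standard deviation
#' @param fwhm full width at half maximum (any length unit).
#' @return sigma in the same unit: `fwhm / (2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Preprocessing parameters
#' @param fwhm_mm smoothing kernel FWHM in mm (>= 0; 0 disables smoothing).
#' @param highpass_cutoff_hz high-pass cutoff frequency in Hz.
#' @param tr_s repetition time in seconds.
#' @return a validated `preproc_params` list.
#' @export
preproc_params <- function(fwhm_mm = 5, highpass_cutoff_hz = 0.01, tr_s = 2.5) {
  stopifnot(fwhm_mm >= 0, tr_s > 0)
  if (!(highpass_cutoff_hz > 0 && highpass_cutoff_hz < 1 / (2 * tr_s)))
    stop("`highpass_cutoff_hz` must lie in (0, Nyquist = ",
         signif(1 / (2 * tr_s), 4), " Hz)")
  structure(list(fwhm_mm = fwhm_mm, highpass_cutoff_hz = highpass_cutoff_hz,
                 tr_s = tr_s), class = "preproc_params")
}

# 1D Gaussian smoothing matrix with whole-sample reflection at the edges.
# Symmetric kernel + mirror boundary conserves the per-volume sum.
gaussian_kernel_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(3.5 * sigma_vox))
  off <- -r:r
  w <- exp(-0.5 * (off / sigma_vox)^2)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_along(off)) {
      j <- i + off[k]
      while (j < 1L || j > n) {
        if (j < 1L) j <- 2L - j
        if (j > n) j <- 2L * n - j
      }
      K[i, j] <- K[i, j] + w[k]
    }
  }
  K
}

smooth_axis <- function(arr, axis, K) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

#' Spatially smooth a 4D image with an isotropic Gaussian
#'
#' Separable per-axis convolution with `sigma_voxels = fwhm_to_sigma(fwhm_mm) /
#' voxel_size` on each axis (anisotropic voxels handled per-axis), reflecting
#' at the boundaries.
#'
#' @param x a `subject_bold`, or a 3D/4D array (then `voxel_mm` is required).
#' @param fwhm_mm kernel FWHM in mm; 0 is the identity.
#' @param voxel_mm voxel size, for plain arrays.
#' @return same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_mm = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (inherits(x, "subject_bold")) {
    x$data <- smooth_gaussian(x$data, fwhm_mm, x$voxel_mm)
    return(x)
  }
  if (is.null(voxel_mm))
    stop("voxel size unknown: pass `voxel_mm` or a subject_bold")
  if (fwhm_mm == 0) return(x)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  arr <- x
  added_dim <- FALSE
  if (length(dim(arr)) == 3L) { dim(arr) <- c(dim(arr), 1L); added_dim <- TRUE }
  for (axis in 1:3) {
    sigma <- fwhm_to_sigma(fwhm_mm) / voxel_mm[axis]
    if (sigma <= 0) next
    K <- gaussian_kernel_matrix(dim(arr)[axis], sigma)
    arr <- smooth_axis(arr, axis, K)
  }
  if (added_dim) dim(arr) <- dim(arr)[1:3]
  arr
}

butter_highpass <- function(cutoff_hz, tr_s, order = 4) {
  nyq <- 0.5 / tr_s
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("high-pass cutoff must lie strictly between 0 and the Nyquist ",
         "frequency (", signif(nyq, 4), " Hz)")
  bt <- signal::butter(order, cutoff_hz / nyq, type = "high")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

# Steady-state initial filter state (direct form II transposed), so that the
# forward and backward passes start without a step transient.
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- matrix(0, n - 1L, n - 1L)   # companion matrix of a, transposed
  comp[1L, ] <- -a[-1L] / a[1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(comp)
  B <- b[-1L] - a[-1L] * b[1L]
  solve(IminusA, B)
}

# IIR filter (direct form II transposed) along rows of X (time x channels),
# with initial state zi scaled by the first sample of each channel.
lfilter_mat <- function(b, a, X, zi) {
  n <- length(a)
  nt <- nrow(X); nc <- ncol(X)
  Z <- zi %o% X[1L, ]
  Y <- matrix(0, nt, nc)
  for (t in seq_len(nt)) {
    xt <- X[t, ]
    yt <- b[1L] * xt + Z[1L, ]
    if (n > 2L)
      for (k in seq_len(n - 2L))
        Z[k, ] <- b[k + 1L] * xt + Z[k + 1L, ] - a[k + 1L] * yt
    Z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# Zero-phase forward-backward filtering with odd (antisymmetric) edge
# extension, columns of X filtered independently.
filtfilt_mat <- function(b, a, X) {
  nt <- nrow(X)
  pad <- 3L * max(length(a), length(b))
  if (nt <= pad + 1L)
    stop("time series too short for zero-phase filtering (need > ",
         pad + 1L, " points)")
  zi <- lfilter_zi(b, a)
  top <- 2 * matrix(X[1L, ], pad, ncol(X), byrow = TRUE) -
    X[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[nt, ], pad, ncol(X), byrow = TRUE) -
    X[(nt - 1L):(nt - pad), , drop = FALSE]
  Xe <- rbind(top, X, bot)
  Y <- lfilter_mat(b, a, Xe, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y <- lfilter_mat(b, a, Y, zi)
  Y <- Y[nrow(Y):1L, , drop = FALSE]
  Y[(pad + 1L):(pad + nt), , drop = FALSE]
}

#' High-pass filter along time
#'
#' Zero-phase (forward-backward) order-4 Butterworth high-pass. Accepts a
#' vector, a (time x series) matrix, or a `subject_bold` (filtered voxelwise).
#'
#' @param x input time series.
#' @param cutoff_hz cutoff frequency in Hz (must be below Nyquist).
#' @param tr_s sampling interval in seconds (taken from a `subject_bold`).
#' @return same shape as `x`.
#' @export
highpass_filter <- function(x, cutoff_hz, tr_s = NULL) {
  if (inherits(x, "subject_bold")) {
    d <- dim(x$data)
    m <- t(matrix(x$data, nrow = prod(d[1:3]), ncol = d[4]))
    m <- highpass_filter(m, cutoff_hz, x$tr_s)
    x$data <- array(t(m), d)
    return(x)
  }
  if (is.null(tr_s)) stop("`tr_s` required for plain inputs")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(X) < 10L) stop("need at least 10 time points")
  co <- butter_highpass(cutoff_hz, tr_s)
  Y <- filtfilt_mat(co$b, co$a, X)
  # remove the residual finite-length mean so output series are zero-mean
  Y <- sweep(Y, 2L, colMeans(Y))
  if (vec) drop(Y) else Y
}

#' Squared-magnitude frequency response of the high-pass filter
#'
#' The gain a pure sinusoid experiences under the zero-phase forward-backward
#' filter, i.e. `|H(f)|^2` of the underlying Butterworth design.
#'
#' @param freq_hz frequencies at which to evaluate the gain.
#' @param cutoff_hz filter cutoff in Hz.
#' @param tr_s sampling interval in seconds.
#' @return numeric gain values in `[0, 1]`.
#' @export
highpass_gain <- function(freq_hz, cutoff_hz, tr_s) {
  co <- butter_highpass(cutoff_hz, tr_s)
  z <- exp(-1i * 2 * pi * freq_hz * tr_s)
  H <- outer(z, seq_along(co$b) - 1L, `^`) %*% co$b /
    (outer(z, seq_along(co$a) - 1L, `^`) %*% co$a)
  as.numeric(Mod(H)^2)
}

#' Preprocess one subject: smooth, then high-pass filter
#' @param subject a `subject_bold`.
#' @param params a [preproc_params()].
#' @return the preprocessed `subject_bold`.
#' @export
preprocess_subject <- function(subject, params = preproc_params(tr_s = subject$tr_s)) {
  stopifnot(inherits(subject, "subject_bold"),
            inherits(params, "preproc_params"))
  out <- smooth_gaussian(subject, params$fwhm_mm)
  highpass_filter(out, params$highpass_cutoff_hz)
}
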