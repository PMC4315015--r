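# Temporal group statistics: time-series amplitude (SD of the raw stage-1
# series), full-correlation network matrices on the Fisher-z scale, and
# two-sample t-tests with family-wise error control by the permutation
# distribution of the maximum |t| within each declared family.

#' Time-series amplitude
#'
#' The sample standard deviation (n - 1 denominator) of a raw stage-1 time
#' course; for a matrix, one amplitude per column. A constant series is
#' flagged with a warning and returns 0.
#'
#' @param ts numeric vector or (volumes x components) matrix (>= 2 rows).
#' @return nonnegative amplitude(s) in signal units.
#' @export
amplitude <- function(ts) {
  if (is.matrix(ts)) return(apply(ts, 2L, amplitude))
  if (length(ts) < 2L) stop("need at least 2 time points")
  s <- stats::sd(ts)
  if (s == 0) {
    warning("constant time series: amplitude 0")
    return(0)
  }
  s
}

#' Network matrix: pairwise full correlation on the Fisher-z scale
#'
#' Pearson correlation between all column pairs, `|r|` capped at `1 - 1e-7`,
#' then Fisher-transformed (`atanh`). The diagonal is `NA`; a zero-variance
#' column gets an `NA` row/column with a warning.
#'
#' @param ts_matrix (volumes x components) matrix, >= 3 rows, >= 2 columns.
#' @param r_cap cap on `|r|` before the Fisher transform.
#' @return symmetric matrix of z-values with `NA` diagonal.
#' @export
netmat <- function(ts_matrix, r_cap = 1 - 1e-7) {
  stopifnot(is.matrix(ts_matrix), nrow(ts_matrix) >= 3L,
            ncol(ts_matrix) >= 2L)
  sds <- apply(ts_matrix, 2L, stats::sd)
  ok <- sds > 0
  z <- matrix(NA_real_, ncol(ts_matrix), ncol(ts_matrix))
  if (any(!ok))
    warning("zero-variance component(s): ",
            paste(which(!ok), collapse = ", "), " set to NA")
  if (sum(ok) >= 2L) {
    r <- stats::cor(ts_matrix[, ok, drop = FALSE])
    r <- pmin(pmax(r, -r_cap), r_cap)
    z[ok, ok] <- atanh(r)
  }
  diag(z) <- NA_real_
  dimnames(z) <- list(colnames(ts_matrix), colnames(ts_matrix))
  z
}

#' Enumerate netmat edges with within/between-network structure
#'
#' @param parent_of integer vector: parent network id of each component.
#' @return data.frame with `i`, `j` (i < j), `name`, `within` (same parent),
#'   and `family` (`"within"`/`"between"`).
#' @export
edge_table <- function(parent_of) {
  n <- length(parent_of)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- parent_of[idx[, 1]] == parent_of[idx[, 2]]
  data.frame(i = idx[, 1], j = idx[, 2],
             name = sprintf("%d~%d", idx[, 1], idx[, 2]),
             within = within,
             family = ifelse(within, "within", "between"))
}

# Random (or exhaustive, for tiny groups) group-A membership indicators.
# Row 1 is always the observed labeling.
perm_indicators <- function(labels, n_perm, seed) {
  n <- length(labels)
  is_a <- labels == levels(factor(labels))[1]
  n_a <- sum(is_a)
  n_comb <- choose(n, n_a)
  if (n_comb <= n_perm) {
    warning("only ", n_comb, " distinct labelings exist; ",
            "using exhaustive enumeration")
    combs <- utils::combn(n, n_a)
    G <- matrix(0, ncol(combs), n)
    G[cbind(rep(seq_len(ncol(combs)), each = n_a), as.vector(combs))] <- 1
    obs <- which(colSums(abs(t(G) - is_a)) == 0)
    G <- rbind(G[obs, ], G[-obs, , drop = FALSE])
  } else {
    set.seed(seed)
    G <- matrix(0, n_perm, n)
    G[1, is_a] <- 1
    for (p in 2:n_perm) G[p, sample(n, n_a)] <- 1
  }
  G
}

# Two-sample t statistics for all permutations at once.
# X: subjects x tests; G: perms x subjects 0/1 indicator of group A.
perm_t_matrix <- function(X, G, welch = FALSE) {
  n <- nrow(X)
  n_a <- sum(G[1, ]); n_b <- n - n_a
  X2 <- X^2
  tot1 <- colSums(X); tot2 <- colSums(X2)
  SA <- G %*% X; SA2 <- G %*% X2
  SB <- matrix(tot1, nrow(G), ncol(X), byrow = TRUE) - SA
  SB2 <- matrix(tot2, nrow(G), ncol(X), byrow = TRUE) - SA2
  mA <- SA / n_a; mB <- SB / n_b
  vA <- (SA2 - n_a * mA^2) / (n_a - 1)
  vB <- (SB2 - n_b * mB^2) / (n_b - 1)
  vA <- pmax(vA, 0); vB <- pmax(vB, 0)
  if (welch) {
    se <- sqrt(vA / n_a + vB / n_b)
  } else {
    sp2 <- ((n_a - 1) * vA + (n_b - 1) * vB) / (n - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  }
  diffm <- mA - mB
  t <- diffm / se
  t[se == 0 & diffm == 0] <- 0
  t[se == 0 & diffm != 0] <- Inf * sign(diffm[se == 0 & diffm != 0])
  t
}

#' Two-sample group comparison with permutation FWE correction
#'
#' Pooled-variance (default) or Welch two-sample t statistic per test;
#' uncorrected p-values come from each test's own permutation distribution of
#' |t|, and family-wise corrected p-values from the permutation distribution
#' of the maximum |t| within the test's declared family. The observed
#' labeling is always included among the permutations, and the whole
#' procedure is deterministic given `seed`. When fewer distinct labelings
#' than `n_perm` exist, all of them are enumerated (with a warning).
#'
#' @param values numeric vector (one test) or (subjects x tests) matrix.
#' @param labels group label per subject (2 levels; first level is "A" in the
#'   `mean_A - mean_B` statistic).
#' @param family family id per test (default: all tests in one family).
#' @param n_perm number of permutations (observed labeling included).
#' @param seed integer seed.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return a `group_comparison` data.frame: `test`, `family`, `statistic`,
#'   `p_uncorr`, `p_fwe`, `mean_A`, `mean_B`, `sd_A`, `sd_B`.
#' @export
compare_groups <- function(values, labels, family = NULL, n_perm = 5000,
                           seed = 1, welch = FALSE) {
  X <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  lev <- levels(factor(labels))
  if (length(lev) != 2L) stop("need exactly two groups")
  if (min(table(labels)) < 2L) stop("need >= 2 subjects per group")
  if (is.null(family)) family <- rep("all", ncol(X))
  if (length(family) == 0L || length(family) != ncol(X))
    stop("`family` must name one family per test")
  G <- perm_indicators(labels, n_perm, derive_seed(seed, "perm-labels"))
  t_all <- perm_t_matrix(X, G, welch = welch)
  t_obs <- t_all[1, ]
  abs_t <- abs(t_all)
  p_unc <- colMeans(sweep(abs_t, 2L, abs(t_obs), `>=`))
  p_fwe <- numeric(ncol(X))
  for (f in unique(family)) {
    cols <- which(family == f)
    maxnull <- apply(abs_t[, cols, drop = FALSE], 1L, max)
    p_fwe[cols] <- vapply(abs(t_obs[cols]),
                          function(v) mean(maxnull >= v), 0)
  }
  is_a <- labels == lev[1]
  out <- data.frame(
    test = if (!is.null(colnames(X))) colnames(X) else
      sprintf("test%d", seq_len(ncol(X))),
    family = family,
    statistic = t_obs,
    p_uncorr = p_unc,
    p_fwe = p_fwe,
    mean_A = colMeans(X[is_a, , drop = FALSE]),
    mean_B = colMeans(X[!is_a, , drop = FALSE]),
    sd_A = apply(X[is_a, , drop = FALSE], 2L, stats::sd),
    sd_B = apply(X[!is_a, , drop = FALSE], 2L, stats::sd),
    row.names = NULL)
  class(out) <- c("group_comparison", "data.frame")
  attr(out, "n_perm") <- nrow(G)
  attr(out, "groups") <- lev
  out
}
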