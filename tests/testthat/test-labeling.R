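test_that("dice coefficient worked cases and conventions", {
  d <- c(4, 4, 2)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:4] <- TRUE; b[1:4] <- TRUE
  expect_equal(dice_coefficient(a, b), 1)
  b[] <- FALSE; b[5:8] <- TRUE
  expect_equal(dice_coefficient(a, b), 0)
  b[] <- FALSE; b[3:6] <- TRUE               # |A|=4, |B|=4, overlap 2
  expect_equal(dice_coefficient(a, b), 0.5)
  expect_equal(dice_coefficient(array(FALSE, d), array(FALSE, d)), 0)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_error(dice_coefficient(a, array(FALSE, c(4, 4, 3))), "grid")
})

test_that("dice_matrix equals the brute-force pairwise loop", {
  set.seed(13)
  d <- c(8, 8, 5)
  high <- array(rnorm(prod(d) * 4, sd = 2), c(d, 4))
  low <- array(rnorm(prod(d) * 3, sd = 2), c(d, 3))
  got <- dice_matrix(high, low, z_thresh = 2)
  expect_equal(unname(got), dice_matrix_oracle(high, low, 2))
  # identical map -> dice 1 at that column
  high2 <- array(c(as.vector(low[, , , 2]), as.vector(high[, , , 2])),
                 c(d, 2))
  got2 <- dice_matrix(high2, low, z_thresh = 2)
  expect_equal(got2[1, 2], 1)
})

test_that("raising the threshold never enlarges masks", {
  set.seed(14)
  d <- c(8, 8, 5)
  maps <- array(rnorm(prod(d) * 3, sd = 2), c(d, 3))
  for (k in 1:3) {
    n3 <- sum(maps[, , , k] > 3)
    n2 <- sum(maps[, , , k] > 2)
    expect_lte(n3, n2)
  }
})

test_that("empty suprathreshold maps warn and give zero rows", {
  d <- c(6, 6, 4)
  high <- array(0, c(d, 2)); high[, , , 1] <- rnorm(prod(d), sd = 3)
  low <- array(rnorm(prod(d), sd = 3), c(d, 1))
  expect_warning(got <- dice_matrix(high, low, z_thresh = 5),
                 "suprathreshold")
  expect_equal(unname(got[2, ]), 0)
})

test_that("temporal correlation averages r arithmetically across subjects", {
  # construct exact correlations from an orthonormal basis
  n <- 40
  u <- sin(2 * pi * seq_len(n) / n); u <- (u - mean(u)) / sd(u)
  v <- cos(2 * pi * seq_len(n) / n); v <- (v - mean(v)) / sd(v)
  mk <- function(r) {
    y <- r * u + sqrt(1 - r^2) * v
    cbind(high = y)
  }
  high_ts <- list(mk(0.2), mk(0.6))
  low_ts <- list(cbind(low = u), cbind(low = u))
  tc <- temporal_corr_matrix(high_ts, low_ts)
  expect_equal(unname(tc[1, 1]), 0.4, tolerance = 1e-10)
  # identical series give exactly 1
  same <- temporal_corr_matrix(low_ts, low_ts)
  expect_equal(unname(same[1, 1]), 1, tolerance = 1e-12)
})

test_that("independent white-noise series have near-zero mean correlation", {
  set.seed(15)
  high_ts <- replicate(20, matrix(rnorm(160 * 2), 160), simplify = FALSE)
  low_ts <- replicate(20, matrix(rnorm(160 * 2), 160), simplify = FALSE)
  tc <- temporal_corr_matrix(high_ts, low_ts)
  expect_lt(max(abs(tc)), 0.1)
})

test_that("zero-variance series exclude subjects with a warning", {
  n <- 30
  a <- matrix(rnorm(n), n); b <- matrix(rnorm(n), n)
  const <- matrix(1, n, 1)
  expect_warning(tc <- temporal_corr_matrix(list(a, const), list(b, b)),
                 "zero-variance")
  expect_equal(unname(tc[1, 1]), cor(a, b)[1, 1])
  expect_error(suppressWarnings(
    temporal_corr_matrix(list(const), list(b))), "all subjects")
})

test_that("labeling follows the spatio-temporal decision rule", {
  ev <- function(dc, tc) match_evidence(rbind(dc), rbind(tc))
  # all Dice below threshold -> residual noise despite strong correlation
  a <- assign_labels(ev(c(0.05, 0.08), c(0.9, 0.2)))
  expect_equal(a$labels$label, "noise")
  # agreeing argmaxes above both thresholds -> that reference network
  b <- assign_labels(ev(c(0.5, 0.1), c(0.7, 0.1)))
  expect_equal(b$labels$label, "1")
  # disagreeing spatial and temporal matches -> unknown
  c_ <- assign_labels(ev(c(0.5, 0.2), c(0.3, 0.6)))
  expect_equal(c_$labels$label, "unknown")
  # temporal max below threshold alone triggers noise under the OR rule
  d_ <- assign_labels(ev(c(0.5, 0.2), c(0.3, 0.2)))
  expect_equal(d_$labels$label, "noise")
  # ... but not under the AND rule (argmaxes agree -> labeled)
  e_ <- assign_labels(ev(c(0.5, 0.2), c(0.3, 0.2)), noise_rule = "and")
  expect_equal(e_$labels$label, "1")
})

test_that("ties break toward the lowest reference index with a message", {
  ev <- match_evidence(rbind(c(0.5, 0.5)), rbind(c(0.7, 0.7)))
  expect_message(a <- assign_labels(ev), "tied")
  expect_equal(a$labels$label, "1")
})

test_that("labels are deterministic and threshold-monotone", {
  set.seed(16)
  for (rep in 1:25) {
    DC <- matrix(round(runif(8 * 3), 2), 8)
    TC <- matrix(round(runif(8 * 3, -1, 1), 2), 8)
    a1 <- suppressMessages(assign_labels(match_evidence(DC, TC)))
    a2 <- suppressMessages(assign_labels(match_evidence(DC, TC)))
    expect_identical(a1$labels, a2$labels)
    # raising thresholds can only move labels toward noise
    hi <- suppressMessages(assign_labels(
      match_evidence(DC, TC, theta_dc = 0.3, theta_tc = 0.6)))
    was_noise <- a1$labels$label == "noise"
    expect_true(all(hi$labels$label[was_noise] == "noise"))
    parentish <- !(a1$labels$label %in% c("noise", "unknown"))
    expect_true(all(hi$labels$label[parentish] %in%
                      c(a1$labels$label[parentish], "noise")))
  }
})

test_that("evidence validation catches shape and range errors", {
  expect_error(match_evidence(matrix(0.5, 2, 2), matrix(0.5, 3, 2)), "shape")
  expect_error(match_evidence(matrix(1.5, 2, 2), matrix(0.5, 2, 2)))
  expect_error(match_evidence(matrix(numeric(0), 0, 0),
                              matrix(numeric(0), 0, 0)), "empty")
})
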