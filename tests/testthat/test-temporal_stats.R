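test_that("amplitude is the sample SD with the documented edge cases", {
  expect_equal(amplitude(c(1, -1, 1, -1)), sqrt(4 / 3))
  x <- rnorm(50)
  expect_equal(amplitude(3 * x), 3 * amplitude(x))
  expect_equal(amplitude(-2 * x), 2 * amplitude(x))
  expect_warning(a0 <- amplitude(rep(5, 10)), "constant")
  expect_equal(a0, 0)
  expect_error(amplitude(1), "2 time points")
  m <- cbind(x, 2 * x)
  expect_equal(unname(amplitude(m)), c(sd(x), 2 * sd(x)))
})

test_that("netmat is the Fisher z of full correlations, capped and NA-safe", {
  set.seed(17)
  x <- rnorm(100)
  ts <- cbind(a = x, b = 0.5 * x + sqrt(0.75) * rnorm(100), c = rnorm(100))
  z <- netmat(ts)
  expect_equal(z[1, 2], atanh(cor(ts)[1, 2]))
  expect_true(all(is.na(diag(z))))
  expect_equal(z, t(z))
  # closed form: r = 0.5 -> z = 0.5493
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # positive affine rescaling of columns changes nothing
  ts2 <- sweep(ts, 2, c(2, 3, 0.5), "*") + 7
  expect_equal(netmat(ts2), netmat(ts), tolerance = 1e-12)
  # perfectly correlated columns stay finite through the cap
  z2 <- netmat(cbind(x, x))
  expect_true(is.finite(z2[1, 2]))
  expect_equal(z2[1, 2], atanh(1 - 1e-7))
  expect_warning(z3 <- netmat(cbind(x, rep(1, 100), rnorm(100))),
                 "zero-variance")
  expect_true(all(is.na(z3[2, ])))
})

test_that("identical group values give t = 0 and corrected p = 1", {
  vals <- rep(c(1, 2, 3, 4), 2)
  labels <- rep(c("A", "B"), each = 4)
  suppressWarnings(res <- compare_groups(vals, labels, n_perm = 200))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_fwe, 1)
  expect_equal(res$p_uncorr, 1)
})

test_that("tiny groups fall back to exhaustive enumeration with a warning", {
  set.seed(18)
  vals <- rnorm(6)
  labels <- rep(c("A", "B"), each = 3)
  expect_warning(res <- compare_groups(vals, labels, n_perm = 5000),
                 "exhaustive")
  expect_equal(attr(res, "n_perm"), choose(6, 3))
})

test_that("permutation p-values are valid and corrected >= uncorrected", {
  set.seed(19)
  X <- matrix(rnorm(40 * 6), 40)
  X[1:20, 1] <- X[1:20, 1] + 2          # one strong effect
  labels <- rep(c("A", "B"), each = 20)
  res <- compare_groups(X, labels, n_perm = 500, seed = 4)
  expect_true(all(res$p_fwe >= res$p_uncorr - 1e-12))
  expect_true(all(res$p_uncorr >= 1 / 500))
  expect_lt(res$p_fwe[1], 0.05)
  expect_gt(res$statistic[1], 0)        # mean_A - mean_B > 0
  r2 <- compare_groups(X, labels, n_perm = 500, seed = 4)
  expect_identical(res, r2)
})

test_that("families are corrected independently", {
  set.seed(20)
  X <- matrix(rnorm(30 * 4), 30)
  labels <- rep(c("A", "B"), each = 15)
  fam <- c("f1", "f1", "f2", "f2")
  res <- compare_groups(X, labels, family = fam, n_perm = 300, seed = 5)
  one <- compare_groups(X[, 1:2], labels, n_perm = 300, seed = 5)
  expect_equal(res$p_fwe[1:2], one$p_fwe)
  expect_error(compare_groups(X, labels, family = character(0)), "family")
})

test_that("welch flag changes the statistic under unequal variances", {
  set.seed(21)
  X <- matrix(c(rnorm(10, sd = 1), rnorm(20, sd = 5)), ncol = 1)
  labels <- rep(c("A", "B"), c(10, 20))
  tp <- compare_groups(X, labels, n_perm = 100, seed = 1)
  tw <- compare_groups(X, labels, n_perm = 100, seed = 1, welch = TRUE)
  expect_false(isTRUE(all.equal(tp$statistic, tw$statistic)))
  # both match t.test on the same data
  expect_equal(tw$statistic,
               unname(t.test(X[1:10], X[11:30])$statistic),
               tolerance = 1e-10)
  expect_equal(tp$statistic,
               unname(t.test(X[1:10], X[11:30], var.equal = TRUE)$statistic),
               tolerance = 1e-10)
})

test_that("planted amplitude reduction lowers group-B mean amplitude", {
  # direction-recovery property at generator effect size d >= 1
  sc <- small_scene(n_per_group = 6, n_volumes = 120, seed = 41)
  amp <- t(vapply(sc$dataset$truth_timecourses, function(m) amplitude(m),
                  numeric(4)))
  groups <- unname(sc$dataset$group_labels)
  affected <- 1   # subnet P1.1 carries amplitude_ratio 0.7
  expect_lt(mean(amp[groups == "B", affected]),
            mean(amp[groups == "A", affected]))
})

test_that("edge_table partitions edges into within and between families", {
  et <- edge_table(c(1, 1, 2, 2, 2))
  expect_equal(nrow(et), 10)
  expect_equal(sum(et$within), 1 + 3)   # C(2,2) + C(3,2)
  expect_setequal(unique(et$family), c("within", "between"))
})
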