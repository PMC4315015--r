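# A noiseless rank-D construction with known maps and courses is the
# linear-algebra oracle for both stages.

make_rank_d <- function(seed = 10, Tn = 50) {
  set.seed(seed)
  grid <- scene_grid(c(10, 10, 6), 3)
  blob <- function(ctr) make_subnet_map(ctr, 6, grid)
  maps <- list(blob(c(3, 3, 3)), blob(c(8, 8, 4)), blob(c(3, 8, 3)))
  M <- vapply(maps, as.vector, numeric(prod(grid$dim)))
  courses <- matrix(rnorm(Tn * 3), Tn, 3) %*%
    chol(matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3))
  X <- courses %*% t(M)
  sub <- subject_bold(array(t(X), c(grid$dim, Tn)), grid$voxel_mm, 2.5)
  mask <- array(TRUE, grid$dim)
  list(sub = sub, M = M, courses = courses, mask = mask, grid = grid,
       maps_arr = array(M, c(grid$dim, 3)))
}

test_that("stage 1 recovers true courses on noiseless rank-D data", {
  rk <- make_rank_d()
  ts <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  # maps are demeaned in the fit; courses recovered up to that projection
  err <- max(abs(ts - rk$courses)) / max(abs(rk$courses))
  expect_lt(err, 1e-8)
})

test_that("stage 1 is invariant to a constant image offset and zero on zeros", {
  rk <- make_rank_d()
  ts1 <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  sub_off <- rk$sub; sub_off$data <- sub_off$data + 11
  ts2 <- stage1_timeseries(sub_off, rk$maps_arr, rk$mask)
  expect_equal(ts1, ts2, tolerance = 1e-8)
  sub0 <- rk$sub; sub0$data[] <- 0
  expect_equal(max(abs(stage1_timeseries(sub0, rk$maps_arr, rk$mask))), 0)
})

test_that("stage 1 rejects rank-deficient map sets naming the pairs", {
  rk <- make_rank_d()
  bad <- array(c(rk$M[, 1], rk$M[, 1], rk$M[, 2]), c(rk$grid$dim, 3))
  expect_error(stage1_timeseries(rk$sub, bad, rk$mask), "collinear")
})

test_that("stage 2 recovers true maps up to scale; des_norm moves amplitude", {
  rk <- make_rank_d()
  ts <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  st2 <- stage2_maps(rk$sub, ts, rk$mask, des_norm = FALSE)
  for (k in 1:3) {
    expect_gt(abs(cor(st2$maps[k, ], rk$M[, k])), 1 - 1e-9)
  }
  # with unit-variance design the coefficient absorbs the course amplitude
  ts_big <- ts; ts_big[, 1] <- ts[, 1] * 3
  st2n <- stage2_maps(rk$sub, ts_big, rk$mask, des_norm = TRUE)
  st2n_ref <- stage2_maps(rk$sub, ts, rk$mask, des_norm = TRUE)
  expect_equal(st2n$maps[1, ], st2n_ref$maps[1, ], tolerance = 1e-8)
})

test_that("stage 2 errors on zero-variance courses and row mismatch", {
  rk <- make_rank_d()
  ts <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  ts0 <- ts; ts0[, 2] <- 5
  expect_error(stage2_maps(rk$sub, ts0, rk$mask), "zero-variance")
  expect_error(stage2_maps(rk$sub, ts[-1, ], rk$mask), "volume count")
})

test_that("permuting course columns permutes stage-2 maps identically", {
  rk <- make_rank_d()
  ts <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  p <- c(3, 1, 2)
  m1 <- stage2_maps(rk$sub, ts, rk$mask)$maps
  m2 <- stage2_maps(rk$sub, ts[, p], rk$mask)$maps
  expect_equal(unname(m2), unname(m1[p, ]), tolerance = 1e-10)
})

matrix_index <- function(ijk, d)
  ijk[1] + d[1] * ((ijk[2] - 1) + d[2] * (ijk[3] - 1))

test_that("single unit-variance course regressed on itself gives beta 1", {
  set.seed(11)
  course <- as.numeric(scale(rnorm(60)))   # mean 0, sample sd 1
  arr <- array(0, c(3, 3, 2, 60))
  arr[2, 2, 1, ] <- course
  sub <- subject_bold(arr, 3, 2.5)
  mask <- array(TRUE, c(3, 3, 2))
  st2 <- stage2_maps(sub, matrix(course, ncol = 1), mask, des_norm = FALSE)
  expect_equal(unname(st2$maps[1, matrix_index(c(2, 2, 1), c(3, 3, 2))]), 1,
               tolerance = 1e-10)
})

test_that("dual regression round-trip explains at least the rank-D variance", {
  sc <- small_scene(n_per_group = 2, n_volumes = 50, seed = 31)
  cc <- concatenate_subjects(sc$dataset$subjects)
  ica <- run_group_ica(cc, 4, seed = 1)
  sub <- sc$dataset$subjects[[1]]
  ts <- stage1_timeseries(sub, ica)
  st2 <- stage2_maps(sub, ts, ica$mask)
  Y <- t(matrix(sub$data, prod(dim(sub$data)[1:3]), dim(sub$data)[4]))
  Y <- Y[, as.vector(ica$mask)]
  Yc <- sweep(Y, 2, colMeans(Y))
  A <- sweep(ts, 2, colMeans(ts)); A <- sweep(A, 2, apply(A, 2, sd), "/")
  fit_dr <- A %*% st2$maps
  resid_dr <- sum((Yc - sweep(fit_dr, 2, colMeans(fit_dr)))^2)
  G <- t(ica$maps)
  fit_grp <- Yc %*% G %*% solve(crossprod(G)) %*% t(G)
  resid_grp <- sum((Yc - fit_grp)^2)
  expect_lte(resid_dr, resid_grp * (1 + 1e-8))
})

test_that("spatial permutation equivariance of stage 2", {
  rk <- make_rank_d()
  ts <- stage1_timeseries(rk$sub, rk$maps_arr, rk$mask)
  st2 <- stage2_maps(rk$sub, ts, rk$mask)
  set.seed(12)
  p <- sample(prod(rk$grid$dim))
  sub_p <- rk$sub
  d <- dim(sub_p$data)
  flat <- matrix(sub_p$data, prod(d[1:3]), d[4])
  sub_p$data <- array(flat[p, ], d)
  st2_p <- stage2_maps(sub_p, ts, rk$mask)
  expect_equal(st2_p$maps, st2$maps[, p], tolerance = 1e-10)
})
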