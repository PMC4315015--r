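grid <- scene_grid(c(12, 12, 8), 2)

test_that("subnet maps are normalized, deterministic, nonnegative blobs", {
  ctr <- c(6, 6, 4)
  m1 <- make_subnet_map(ctr, radius_mm = 6, grid = grid)
  m2 <- make_subnet_map(ctr, radius_mm = 6, grid = grid)
  expect_identical(m1, m2)
  expect_equal(m1[6, 6, 4], 1)
  expect_true(all(m1 >= 0))
  expect_gt(sum(m1), 0)
  expect_lt(m1[1, 1, 1], 1e-3)
  expect_error(make_subnet_map(c(0, 6, 4), 6, grid), "outside")
  expect_error(make_subnet_map(c(6, 6, 40), 6, grid), "outside")
})

test_that("network_spec validates its invariants", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  expect_s3_class(network_spec(1, list(blob)), "network_spec")
  expect_error(network_spec(1, list(blob), parent_coupling = 1.2), "0, 1")
  expect_error(network_spec(1, list(blob), group_amplitude_ratio = 0), "> 0")
  expect_error(network_spec(1, list(blob * 0 + 0.1)), "suprathreshold")
  expect_error(network_spec(1, list(blob), parent_coupling = NA), "finite")
})

test_that("fully coupled subnets share one time course", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  spec <- network_spec(1, list(blob, blob), parent_coupling = 1)
  tc <- make_timecourses(200, list(spec), group = "A", seed = 3)
  expect_equal(unname(cor(tc)[1, 2]), 1)
})

test_that("uncoupled subnets decorrelate as the series grows", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  spec <- network_spec(1, list(blob, blob, blob), parent_coupling = 0)
  tc <- make_timecourses(10000, list(spec), group = "A", seed = 4)
  cc <- cor(tc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("within-parent correlation approaches the coupling product", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  spec <- network_spec(1, list(blob, blob), parent_coupling = c(0.9, 0.6))
  tc <- make_timecourses(10000, list(spec), group = "A", seed = 5)
  expect_equal(unname(cor(tc)[1, 2]), 0.9 * 0.6, tolerance = 0.05)
})

test_that("group-B amplitude ratio scales the sample SD", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  spec <- network_spec(1, list(blob), group_amplitude_ratio = 0.7)
  tA <- make_timecourses(10000, list(spec), group = "A", seed = 6)
  tB <- make_timecourses(10000, list(spec), group = "B", seed = 6)
  expect_equal(sd(tB[, 1]) / sd(tA[, 1]), 0.7, tolerance = 1e-10)
})

test_that("noiseless data are rank-limited by the subnet count", {
  sc <- small_scene(n_per_group = 2, n_volumes = 30, noise_sd = 0)
  sub <- sc$dataset$subjects[[1]]
  d <- dim(sub$data)
  m <- matrix(sub$data, prod(d[1:3]), d[4])
  sv <- svd(m, nu = 0, nv = 0)$d
  expect_lt(sv[5] / sv[1], 1e-10)   # 4 subnets planted
})

test_that("one planted subnet makes every voxel series proportional to it", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  spec <- network_spec(1, list(blob))
  ds <- generate_dataset(2, grid, list(spec), noise_sd = 0, n_volumes = 40,
                         seed = 7)
  sub <- ds$subjects[[1]]
  tc <- ds$truth_timecourses[[1]][, 1]
  active <- which(blob > 0.2, arr.ind = TRUE)
  for (k in seq_len(min(5, nrow(active)))) {
    v <- sub$data[active[k, 1], active[k, 2], active[k, 3], ]
    expect_equal(abs(cor(v, tc)), 1, tolerance = 1e-10)
  }
})

test_that("datasets are reproducible from the seed, including files", {
  sc1 <- small_scene(n_per_group = 2, n_volumes = 20, seed = 9)
  sc2 <- small_scene(n_per_group = 2, n_volumes = 20, seed = 9)
  expect_identical(sc1$dataset$subjects[[3]]$data,
                   sc2$dataset$subjects[[3]]$data)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  write_dataset(sc1$dataset, d1); write_dataset(sc2$dataset, d2)
  f1 <- file.path(d1, "sub-01.nii.gz"); f2 <- file.path(d2, "sub-01.nii.gz")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_dataset(d1)
  expect_equal(back$subjects[[1]]$data,
               sc1$dataset$subjects[[1]]$data, tolerance = 1e-6)
  expect_identical(unname(back$group_labels),
                   unname(sc1$dataset$group_labels))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a voxel far from every subnet carries only noise", {
  sc <- small_scene(n_per_group = 2, n_volumes = 160, noise_sd = 1.5)
  sub <- sc$dataset$subjects[[1]]
  far <- sc$dataset$truth_maps
  support <- apply(far, 1:3, max) < 1e-4
  idx <- which(support, arr.ind = TRUE)
  sds <- vapply(seq_len(min(200, nrow(idx))), function(k)
    sd(sub$data[idx[k, 1], idx[k, 2], idx[k, 3], ]), 0)
  expect_equal(mean(sds), 1.5, tolerance = 0.03)
})

test_that("overlapping parents are rejected unless explicitly allowed", {
  blob <- make_subnet_map(c(6, 6, 4), 6, grid)
  specs <- list(network_spec(1, list(blob)), network_spec(2, list(blob)))
  expect_error(generate_dataset(2, grid, specs, n_volumes = 20), "overlap")
  expect_s3_class(generate_dataset(2, grid, specs, n_volumes = 20,
                                   allow_overlap = TRUE),
                  "synthetic_dataset")
})
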