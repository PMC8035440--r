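make_maps <- function(values_per_subject, dims, mask) {
  lapply(values_per_subject, function(v) {
    arr <- array(0, dims)
    arr[which(mask)] <- v
    arr
  })
}

test_that("one-sample t matches the hand formula and its symmetries", {
  dims <- c(2, 1, 1)
  mask <- array(TRUE, dims)
  st <- one_sample_t(make_maps(list(c(1, 0), c(2, 0), c(3, 0)), dims, mask),
                     mask)
  expect_equal(st$t_values[1, 1, 1], 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(st$t_values[1, 1, 1], 3.4641, tolerance = 1e-4)
  expect_equal(st$df, 2L)
  # zero-variance voxel flagged with t = 0
  expect_equal(st$t_values[2, 1, 1], 0)
  expect_equal(attr(st, "n_zero_variance"), 1L)
  neg <- one_sample_t(make_maps(list(c(-1, 0), c(-2, 0), c(-3, 0)), dims, mask),
                      mask)
  expect_equal(neg$t_values, -st$t_values, tolerance = 1e-12)
  expect_error(one_sample_t(make_maps(list(1), c(1, 1, 1),
                                      array(TRUE, c(1, 1, 1))),
                            array(TRUE, c(1, 1, 1))), "at least 2")
})

test_that("two-sample t equals the textbook pooled formula and t.test", {
  dims <- c(1, 1, 1)
  mask <- array(TRUE, dims)
  a <- make_maps(list(1, 2, 3), dims, mask)
  b <- make_maps(list(4, 5, 6), dims, mask)
  st <- two_sample_t(a, b, mask)
  expect_equal(st$t_values[1, 1, 1], -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(st$t_values[1, 1, 1], -3.6742, tolerance = 1e-4)
  expect_equal(st$df, 4L)
  sw <- two_sample_t(b, a, mask)
  expect_equal(sw$t_values, -st$t_values, tolerance = 1e-12)
  ident <- two_sample_t(a, a, mask)
  expect_equal(ident$t_values[1, 1, 1], 0)

  # oracle: stats::t.test with pooled variance, random voxels
  dims <- c(4, 3, 2)
  mask <- withr::with_seed(3, array(runif(24) < 0.8, dims))
  va <- withr::with_seed(4, replicate(5, rnorm(sum(mask)), simplify = FALSE))
  vb <- withr::with_seed(5, replicate(7, rnorm(sum(mask)), simplify = FALSE))
  st2 <- two_sample_t(make_maps(va, dims, mask), make_maps(vb, dims, mask),
                      mask)
  idx <- which(mask)
  for (k in c(1, 3, sum(mask))) {
    ref <- t.test(vapply(va, `[`, numeric(1), k),
                  vapply(vb, `[`, numeric(1), k), var.equal = TRUE)
    expect_equal(st2$t_values[idx[k]], unname(ref$statistic),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo extent threshold is deterministic and sane", {
  g <- grid_geometry(c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  p <- correction_params(n_simulations = 1000, fwhm_mm = 0, seed = 7)
  k1 <- cluster_extent_threshold(mask, g, p)
  k2 <- cluster_extent_threshold(mask, g, p)
  expect_identical(k1, k2)
  # independent-voxel null at voxel p = .01 two-tailed on 64 voxels:
  # singletons arise in ~47% of volumes, adjacent pairs in ~4%, so the
  # threshold must exceed 1 and stay small
  expect_gte(k1, 2L)
  expect_lte(k1, 4L)
  expect_warning(cluster_extent_threshold(mask, g,
                                          correction_params(n_simulations = 50,
                                                            fwhm_mm = 0)),
                 "100")
  expect_error(cluster_extent_threshold(array(FALSE, c(4, 4, 4)), g, p),
               "empty")
})

test_that("wider smoothing never shrinks the extent threshold", {
  g <- grid_geometry(c(10, 10, 10))
  mask <- make_tissue_masks(g)$whole_brain
  ks <- vapply(c(0, 6, 12), function(fw) {
    mean(vapply(1:3, function(s)
      cluster_extent_threshold(mask, g,
                               correction_params(n_simulations = 200,
                                                 fwhm_mm = fw, seed = s)),
      numeric(1)))
  }, numeric(1))
  expect_true(ks[1] <= ks[2] && ks[2] <= ks[3])
})

test_that("cluster extraction thresholds, filters by extent, and sorts", {
  g <- grid_geometry(c(8, 8, 8))
  mask <- array(TRUE, c(8, 8, 8))
  p <- correction_params()
  zero <- stat_map(array(0, c(8, 8, 8)), 18L, mask, "null")
  expect_equal(nrow(extract_clusters(zero, p, 2, g)), 0)

  # one 40-voxel positive blob against extent threshold 50: filtered out
  tv <- array(0, c(8, 8, 8))
  blob <- as.matrix(expand.grid(1:4, 1:5, 1:2))
  tv[blob] <- 5
  st <- stat_map(tv, 18L, mask, "blob")
  expect_equal(nrow(extract_clusters(st, p, 50, g)), 0)

  # two blobs of opposite sign: sorted by |peak t|, peak voxel correct
  tv[blob] <- 4
  tv[2, 2, 1] <- 6.5
  tv[6:8, 6:8, 6:8] <- -8
  st <- stat_map(tv, 18L, mask, "two blobs")
  ct <- extract_clusters(st, p, 2, g)
  expect_equal(nrow(ct), 2)
  expect_equal(ct$sign, c("negative", "positive"))
  expect_equal(ct$size_voxels, c(27L, 40L))
  expect_equal(ct$peak_t, c(-8, 6.5))
  expect_equal(unlist(ct[2, c("peak_x_mm", "peak_y_mm", "peak_z_mm")]),
               voxel_to_world(g, matrix(c(2, 2, 1), 1))[1, ],
               ignore_attr = TRUE)
  # every cluster voxel exceeds the voxel-level threshold
  tcut <- qt(1 - p$voxel_p / 2, 18)
  for (vx in attr(ct, "voxels")) expect_true(all(abs(tv[vx]) > tcut))
  # positive and negative blobs are never merged even when adjacent
  expect_equal(length(attr(ct, "voxels")[[1]]), 27)
})

test_that("connectivity settings change component structure as expected", {
  arr <- array(FALSE, c(4, 4, 1))
  arr[1, 1, 1] <- TRUE
  arr[2, 2, 1] <- TRUE   # diagonal touch
  c26 <- fcdensity:::label_components(arr, 26L)
  c6 <- fcdensity:::label_components(arr, 6L)
  expect_length(c26, 1)
  expect_length(c6, 2)
})

test_that("smoothness estimation recovers the applied kernel width", {
  g <- grid_geometry(c(20, 20, 20))
  mask <- make_tissue_masks(g)$whole_brain
  sig <- rep(fcdensity:::fwhm_to_sigma(6) / 3, 3)
  maps <- withr::with_seed(8, replicate(6, {
    n <- fcdensity:::gauss_smooth3d(array(rnorm(8000), c(20, 20, 20)), sig)
    (n - mean(n[mask])) / sd(n[mask])
  }, simplify = FALSE))
  fw <- estimate_smoothness(maps, mask, g)
  expect_true(all(abs(fw - 6) < 0.8))
})
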