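test_that("neighbourhood offsets enumerate the world-distance sphere", {
  o <- neighborhood_offsets(c(3, 3, 3), 6)
  expect_equal(nrow(o), 32)
  # exhaustive lattice check over [-2, 2]^3
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  d2 <- rowSums((g * 3)^2)
  expect_equal(nrow(o), sum(d2 > 0 & d2 <= 36))
  expect_true(all(rowSums((o * 3)^2) <= 36))
  expect_equal(nrow(neighborhood_offsets(c(3, 3, 3), 0)), 0)
  expect_equal(nrow(neighborhood_offsets(c(1, 1, 1), 1)), 6)
  # anisotropic voxels use world distance
  expect_equal(nrow(neighborhood_offsets(c(1, 2, 2), 1)), 2)
})

test_that("streamed FCD equals the brute-force correlation matrix oracle", {
  withr::with_seed(42, {
    for (i in 1:6) {
      dims <- sample(4:8, 3, replace = TRUE)
      tt <- sample(c(20, 50), 1)
      g <- grid_geometry(dims)
      run <- bold_run(array(rnorm(prod(dims) * tt), c(dims, tt)), g, 2)
      gray <- array(runif(prod(dims)) < 0.7, dims)
      gray[1, 1, 1] <- TRUE
      p <- fcd_params(r_threshold = sample(c(0.25, 0.3), 1),
                      radius_mm = sample(c(3, 6, 9), 1))
      a <- compute_fcd(run, gray, p, block_size = 17L)
      b <- brute_force_fcd(run, gray, p)
      expect_same_maps(a, b)
      # conservation: local + long = total degree over all gray voxels
      tot <- compute_fcd(run, gray, fcd_params(p$r_threshold, 1e6, 6))
      expect_equal(a$local$values + a$long_range$values,
                   tot$local$values, tolerance = 0)
    }
  })
})

test_that("local/long split follows world distance through the affine", {
  # 1x1x4 line of voxels at 3 mm: v1 and v4 share a sinusoid (9 mm apart),
  # v2 and v3 are exactly orthogonal to everything
  tt <- 16
  g <- grid_geometry(c(1, 1, 4))
  s <- sin(2 * pi * seq_len(tt) / 8)
  q <- withr::with_seed(9, qr.Q(qr(cbind(s, 1, matrix(rnorm(tt * 2), tt)))))
  dat <- array(0, c(1, 1, 4, tt))
  dat[1, 1, 1, ] <- s
  dat[1, 1, 4, ] <- s
  dat[1, 1, 2, ] <- q[, 3]
  dat[1, 1, 3, ] <- q[, 4]
  run <- bold_run(dat, g, 2)
  f <- compute_fcd(run, array(TRUE, c(1, 1, 4)), fcd_params())
  expect_equal(f$local$values[1, 1, 1], 0)
  expect_equal(f$long_range$values[1, 1, 1], 1)
  expect_equal(f$long_range$values[1, 1, 4], 1)

  # two perfectly correlated voxels 3 mm apart: one local edge each
  g2 <- grid_geometry(c(2, 1, 1))
  dat2 <- array(rep(s, each = 2), c(2, 1, 1, tt))
  f2 <- compute_fcd(bold_run(dat2, g2, 2), array(TRUE, c(2, 1, 1)),
                    fcd_params())
  expect_equal(as.numeric(f2$local$values), c(1, 1))
  expect_equal(as.numeric(f2$long_range$values), c(0, 0))
})

test_that("degenerate series yield no edges and tiny inputs error", {
  g <- grid_geometry(c(2, 2, 1))
  const <- bold_run(array(5, c(2, 2, 1, 20)), g, 2)
  mask <- array(TRUE, c(2, 2, 1))
  expect_message(f <- compute_fcd(const, mask, fcd_params()),
                 "zero-variance")
  expect_true(all(f$local$values == 0) && all(f$long_range$values == 0))
  b <- brute_force_fcd(const, mask, fcd_params())
  expect_same_maps(f, b)

  single <- array(FALSE, c(2, 2, 1)); single[1, 1, 1] <- TRUE
  run <- tiny_run(c(2, 2, 1), tt = 20, seed = 1)
  bs <- brute_force_fcd(run, single, fcd_params())
  expect_true(all(bs$local$values == 0) && all(bs$long_range$values == 0))

  short <- tiny_run(c(2, 2, 1), tt = 2, seed = 1)
  expect_error(compute_fcd(short, mask, fcd_params()), "3 timepoints")
})

test_that("counts are monotone in threshold and radius", {
  run <- tiny_run(c(6, 6, 6), tt = 30, seed = 10)
  gray <- array(TRUE, c(6, 6, 6))
  lo <- compute_fcd(run, gray, fcd_params(r_threshold = 0.25))
  hi <- compute_fcd(run, gray, fcd_params(r_threshold = 0.4))
  expect_true(all(hi$local$values <= lo$local$values))
  expect_true(all(hi$long_range$values <= lo$long_range$values))
  r3 <- compute_fcd(run, gray, fcd_params(radius_mm = 3))
  r9 <- compute_fcd(run, gray, fcd_params(radius_mm = 9))
  expect_true(all(r9$local$values >= r3$local$values))
  expect_true(all(r9$long_range$values <= r3$long_range$values))
})

test_that("maps transform covariantly under a grid reflection", {
  dims <- c(5, 4, 3)
  run <- tiny_run(dims, tt = 25, seed = 11)
  gray <- withr::with_seed(12, array(runif(prod(dims)) < 0.8, dims))
  f <- compute_fcd(run, gray, fcd_params())
  flip <- function(a) a[rev(seq_len(dims[1])), , , drop = FALSE]
  run2 <- bold_run(run$data[rev(seq_len(dims[1])), , , , drop = FALSE],
                   run$geometry, run$tr_s)
  f2 <- compute_fcd(run2, flip(gray), fcd_params())
  expect_equal(f2$local$values, flip(f$local$values), tolerance = 0)
  expect_equal(f2$long_range$values, flip(f$long_range$values), tolerance = 0)
})

test_that("normalization divides by the mask mean and standardizes", {
  dims <- c(3, 1, 1)
  mask <- array(TRUE, dims)
  m <- raw_map_with(c(1, 2, 3), mask, dims)
  z <- normalize_fcd(m, mask)
  expect_equal(as.numeric(z$values), c(-1, 0, 1) * sqrt(3 / 2),
               tolerance = 1e-6)
  expect_equal(as.numeric(z$values)[1], -1.2247, tolerance = 1e-4)
  # scale invariance: x and 2x give identical Z maps
  z2 <- normalize_fcd(raw_map_with(c(2, 4, 6), mask, dims), mask)
  expect_equal(z$values, z2$values, tolerance = 1e-12)
  # within-mask mean 0, sd 1 on a larger random map
  big <- withr::with_seed(13, raw_map_with(rpois(64, 5), array(TRUE, c(4, 4, 4)),
                                           c(4, 4, 4)))
  zb <- normalize_fcd(big, big$mask)
  v <- zb$values[big$mask]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)
  expect_error(normalize_fcd(raw_map_with(c(0, 0, 0), mask, dims), mask),
               "no connections")
  expect_error(normalize_fcd(raw_map_with(c(2, 2, 2), mask, dims), mask),
               "degenerate")
})

test_that("Gaussian smoothing matches the closed-form kernel profile", {
  g <- grid_geometry(c(15, 15, 15))
  mask <- array(TRUE, g$dims)
  imp <- array(0, g$dims); imp[8, 8, 8] <- 1
  m <- fcd_map(imp, "local", fcd_params(), mask, "normalized")
  sm <- smooth_map(m, 6, g)
  # 6 mm FWHM on a 3 mm grid: a face neighbour sits at FWHM/2, i.e. at half
  # maximum of the Gaussian profile
  ratio <- sm$values[9, 8, 8] / sm$values[8, 8, 8]
  sig <- 6 / (2 * sqrt(2 * log(2)))
  expect_equal(ratio, exp(-9 / (2 * sig^2)), tolerance = 0.01)
  expect_equal(ratio, 0.5, tolerance = 0.01)
  expect_equal(sm$values[8, 9, 8], sm$values[9, 8, 8], tolerance = 1e-12)
  expect_equal(sm$values[8, 8, 7], sm$values[9, 8, 8], tolerance = 1e-12)

  # constant map is unchanged under mask-renormalized smoothing
  masks <- make_tissue_masks(g)
  cm <- fcd_map(masks$gray * 2.5, "local", fcd_params(), masks$gray,
                "normalized")
  smc <- smooth_map(cm, 6, g)
  expect_equal(smc$values[masks$gray], rep(2.5, sum(masks$gray)),
               tolerance = 1e-9)
  expect_true(all(smc$values[!masks$gray] == 0))

  # vanishing kernel width approaches the identity
  sm0 <- smooth_map(m, 1e-9, g)
  expect_equal(sm0$values, imp, tolerance = 1e-9)
})

test_that("a planted local hub stands out of the smoothed lFCD map", {
  spec <- default_study_spec(n_per_group = 1, seed = 99)
  masks <- make_tissue_masks(spec$geometry)
  s <- generate_subject(spec, "A", 1)
  pp <- preprocess_subject(s$bold, s$motion, masks)
  maps <- subject_fcd(pp$run, masks$gray)
  hub <- spec$local_hubs$A[[1]]$center
  lin <- fcdensity:::ijk_to_linear(matrix(hub, 1), spec$geometry$dims)
  v <- maps$local$values[masks$gray]
  z_gap <- (maps$local$values[lin] - median(v)) /
    sqrt(mean((v - mean(v))^2))
  expect_gt(z_gap, 2)
})
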