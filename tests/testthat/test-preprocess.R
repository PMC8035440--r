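test_that("initial volumes are dropped from run and motion together", {
  run <- tiny_run(c(4, 4, 4), tt = 240, seed = 1)
  mo <- motion_params(matrix(rnorm(240 * 6), 240, 6))
  dr <- drop_initial_volumes(run, mo, 10)
  expect_equal(dim(dr$run$data)[4], 230)
  expect_equal(nrow(dr$motion$translations_mm), 230)
  expect_equal(dr$run$data[, , , 1], run$data[, , , 11])
  expect_equal(dr$motion$translations_mm[1, ],
               mo$translations_mm[11, ])

  id <- drop_initial_volumes(run, mo, 0)
  expect_identical(id$run$data, run$data)

  short <- tiny_run(c(4, 4, 4), tt = 5, seed = 2)
  expect_error(drop_initial_volumes(short, zero_motion(5), 10), "drop")
})

test_that("motion exclusion is strict at the 1.5 mm / 1.5 degree limits", {
  tt <- 50
  expect_true(motion_exceeds_limits(motion_peaking_at(tt, 1.6)))
  expect_false(motion_exceeds_limits(motion_peaking_at(tt, 1.4, 1.0)))
  expect_false(motion_exceeds_limits(motion_peaking_at(tt, 1.5)))   # "more than"
  expect_false(motion_exceeds_limits(motion_peaking_at(tt, 0, 1.5)))
  expect_true(motion_exceeds_limits(motion_peaking_at(tt, 0, 1.6)))
  bad <- motion_peaking_at(tt, NA)
  expect_error(motion_exceeds_limits(bad), "finite")
})

test_that("Friston-24 expansion has the documented column structure", {
  tt <- 20
  m <- matrix(rnorm(tt * 6), tt, 6)
  fr <- friston24(motion_params(m))
  expect_equal(dim(fr$columns), c(tt, 24L))
  # lag block: row i equals parameter at i-1, first row zero
  expect_equal(unname(fr$columns[1, 7:12]), rep(0, 6))
  expect_equal(unname(fr$columns[5, 7:12]), unname(m[4, ]))
  # squares
  expect_equal(unname(fr$columns[, 13:18]), unname(m^2))
  expect_equal(unname(fr$columns[3, 19:24]), unname(m[2, ]^2))
  z <- friston24(zero_motion(tt))
  expect_true(all(z$columns == 0))
})

test_that("nuisance design appends tissue means and their derivatives", {
  g <- grid_geometry(c(8, 8, 8))
  masks <- make_tissue_masks(g)
  tt <- 30
  gt <- sin(seq_len(tt))
  run <- bold_run(array(rep(gt, each = prod(g$dims)), c(g$dims, tt)), g, 2)
  des <- build_nuisance(run, masks, zero_motion(tt))
  expect_equal(ncol(des$columns), 30L)
  expect_equal(unname(des$columns[, "global"]), gt)
  # derivative convention: first difference, zero-padded
  expect_equal(unname(des$columns[, "global_deriv"]), c(0, diff(gt)))
  # WM column equals brute-force masked average on a random run
  run2 <- tiny_run(c(8, 8, 8), tt = tt, seed = 3)
  des2 <- build_nuisance(run2, masks, zero_motion(tt))
  m <- t(matrix(run2$data, prod(g$dims), tt))
  expect_equal(unname(des2$columns[, "wm"]),
               unname(rowMeans(m[, which(masks$white)])))
  empty <- masks
  empty$csf[] <- FALSE
  expect_error(build_nuisance(run2, empty, zero_motion(tt)), "csf")
})

test_that("nuisance regression produces residuals orthogonal to the design", {
  tt <- 40
  run <- tiny_run(c(4, 4, 4), tt = tt, seed = 4)
  X <- matrix(rnorm(tt * 5), tt, 5)
  des <- structure(list(columns = X, column_names = paste0("c", 1:5)),
                   class = "nuisance_design")
  # a voxel equal to a design column is annihilated
  run$data[1, 1, 1, ] <- X[, 2]
  out <- nuisance_regress(run, des)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-8)
  m <- t(matrix(out$data, 64, tt))
  expect_lt(max(abs(crossprod(X, m))), 1e-8)
  expect_lt(max(abs(colSums(m))), 1e-8)  # intercept included

  # all-zero design: dependent columns dropped with a warning; residual is
  # the series minus its mean
  z <- structure(list(columns = matrix(0, tt, 3),
                      column_names = paste0("z", 1:3)),
                 class = "nuisance_design")
  run2 <- tiny_run(c(2, 2, 2), tt = tt, seed = 5)
  expect_warning(out2 <- nuisance_regress(run2, z), "dependent")
  m2 <- t(matrix(run2$data, 8, tt))
  expect_equal(t(matrix(out2$data, 8, tt)), sweep(m2, 2, colMeans(m2)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("detrend+bandpass keeps in-band tones and removes drifts", {
  tt <- 230
  g <- grid_geometry(c(2, 2, 1))
  tp <- seq_len(tt) * 2  # seconds, TR = 2
  tone_in <- sin(2 * pi * 0.05 * tp)
  tone_out <- sin(2 * pi * 0.2 * tp)
  ramp <- 3 * seq_len(tt) + 7
  dat <- array(0, c(2, 2, 1, tt))
  dat[1, 1, 1, ] <- tone_in
  dat[2, 1, 1, ] <- tone_out
  dat[1, 2, 1, ] <- ramp
  run <- bold_run(dat, g, 2)
  out <- detrend_bandpass(run)
  amp <- function(x, f) abs(fft(x))[round(f * tt * 2) + 1]
  expect_gt(amp(out$data[1, 1, 1, ], 0.05) / amp(tone_in, 0.05), 0.9)
  expect_lt(amp(out$data[2, 1, 1, ], 0.2) / amp(tone_out, 0.2), 0.1)
  expect_lt(max(abs(out$data[1, 2, 1, ])), 0.01 * diff(range(ramp)))
  # idempotent in band content: filtering twice changes the tone by < 1%
  out2 <- detrend_bandpass(out)
  expect_lt(abs(amp(out2$data[1, 1, 1, ], 0.05) -
                amp(out$data[1, 1, 1, ], 0.05)) /
            amp(out$data[1, 1, 1, ], 0.05), 0.01)
  expect_error(detrend_bandpass(run, 0.01, 0.3), "Nyquist")
})

test_that("the subject chain equals the operation-by-operation path", {
  g <- grid_geometry(c(10, 10, 10))
  spec <- synthetic_spec(geometry = g, n_timepoints = 60, n_per_group = 1,
                         seed = 6)
  s <- generate_subject(spec, "A", 1)
  masks <- make_tissue_masks(g)
  pp <- preprocess_subject(s$bold, s$motion, masks)
  expect_false(pp$excluded)
  expect_true(all(is.finite(pp$run$data)))
  dr <- drop_initial_volumes(s$bold, s$motion, 10)
  ref <- nuisance_regress(dr$run, build_nuisance(dr$run, masks, dr$motion))
  ref <- detrend_bandpass(ref)
  wb <- which(masks$whole_brain)
  m1 <- matrix(pp$run$data, prod(g$dims))[wb, ]
  m2 <- matrix(ref$data, prod(g$dims))[wb, ]
  expect_equal(m1, m2, tolerance = 1e-12)
  # outside the brain the chain outputs zeros
  expect_true(all(pp$run$data[!masks$whole_brain] == 0))
})

test_that("high-motion subjects are flagged for exclusion by the chain", {
  g <- grid_geometry(c(8, 8, 8))
  spec <- synthetic_spec(geometry = g, n_timepoints = 40, n_per_group = 1,
                         seed = 7)
  s <- generate_subject(spec, "A", 1)
  bad <- motion_peaking_at(40, 1.6)
  pp <- preprocess_subject(s$bold, bad, make_tissue_masks(g))
  expect_true(pp$excluded)
  expect_null(pp$run)
})
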