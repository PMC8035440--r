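# Small in-memory fixtures shared across test files.

tiny_run <- function(dims = c(6, 6, 6), tt = 50, seed = 1, tr_s = 2,
                     fill = NULL) {
  g <- grid_geometry(dims)
  dat <- if (is.null(fill)) {
    withr::with_seed(seed, array(rnorm(prod(dims) * tt), c(dims, tt)))
  } else array(fill, c(dims, tt))
  bold_run(dat, g, tr_s)
}

zero_motion <- function(tt) motion_params(matrix(0, tt, 6))

# Motion trace that peaks at the given translation (mm) on axis x.
motion_peaking_at <- function(tt, peak_mm, peak_deg = 0) {
  m <- matrix(0, tt, 6)
  m[ceiling(tt / 2), 1] <- peak_mm
  m[ceiling(tt / 2), 4] <- peak_deg
  motion_params(m)
}

# A raw-count fcd_map over an explicit mask with given in-mask values.
raw_map_with <- function(values_in_mask, mask, dims) {
  arr <- array(0, dims)
  arr[which(mask)] <- values_in_mask
  fcd_map(arr, "local", fcd_params(), mask, "raw_count")
}

expect_same_maps <- function(a, b) {
  expect_equal(a$local$values, b$local$values, tolerance = 0)
  expect_equal(a$long_range$values, b$long_range$values, tolerance = 0)
}
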