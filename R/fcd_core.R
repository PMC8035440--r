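#' FCD computation parameters
#'
#' @param r_threshold Pearson correlation threshold; an edge requires
#'   r strictly greater than this (default 0.3).
#' @param radius_mm neighbourhood sphere radius in mm separating local
#'   (distance <= radius, inclusive) from long-range (> radius) connections
#'   (default 6).
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (default 6).
#' @return An `fcd_params` object.
#' @export
fcd_params <- function(r_threshold = 0.3, radius_mm = 6, fwhm_mm = 6) {
  stopifnot(r_threshold > 0, r_threshold < 1, radius_mm > 0, fwhm_mm > 0)
  structure(list(r_threshold = r_threshold, radius_mm = radius_mm,
                 fwhm_mm = fwhm_mm), class = "fcd_params")
}

#' One subject's FCD map
#'
#' @param values 3D numeric array: degree counts (`raw_count` stage) or
#'   normalized Z units.
#' @param kind `"local"` or `"long_range"`.
#' @param params the [fcd_params()] that produced the map.
#' @param mask logical gray-matter mask array.
#' @param stage `"raw_count"`, `"normalized"` or `"smoothed"`.
#' @return An `fcd_map` object.
#' @export
fcd_map <- function(values, kind, params, mask, stage) {
  stopifnot(kind %in% c("local", "long_range"),
            stage %in% c("raw_count", "normalized", "smoothed"))
  structure(list(values = values, kind = kind, params = params,
                 mask = mask, stage = stage), class = "fcd_map")
}

#' Integer voxel offsets within a world-distance sphere
#'
#' All nonzero integer lattice offsets (dx, dy, dz) whose Euclidean world
#' distance sqrt((dx*sx)^2 + (dy*sy)^2 + (dz*sz)^2) is at most `radius_mm`;
#' the self offset (0,0,0) is excluded. For a 3 mm isotropic grid and a
#' 6 mm radius this is the 32-point neighbourhood.
#'
#' @param voxel_size_mm positive real triple.
#' @param radius_mm sphere radius in mm (>= 0).
#' @return n x 3 integer matrix of offsets (possibly 0 rows).
#' @export
neighborhood_offsets <- function(voxel_size_mm, radius_mm) {
  stopifnot(radius_mm >= 0, all(voxel_size_mm > 0))
  k <- floor(radius_mm / voxel_size_mm)
  g <- as.matrix(expand.grid(dx = -k[1]:k[1], dy = -k[2]:k[2], dz = -k[3]:k[3]))
  d2 <- (g[, 1] * voxel_size_mm[1])^2 + (g[, 2] * voxel_size_mm[2])^2 +
    (g[, 3] * voxel_size_mm[3])^2
  g[d2 > 0 & d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

# Row-standardize a voxels x time matrix so that X %*% t(X) gives Pearson
# correlations. Zero-variance rows become all-zero (no edges).
standardize_rows <- function(y) {
  cy <- y - rowMeans(y)
  ss <- sqrt(rowSums(cy^2))
  zero <- ss <= 0 | !is.finite(ss)
  ss[zero] <- 1
  x <- cy / ss
  x[zero, ] <- 0
  attr(x, "zero_variance") <- which(zero)
  x
}

#' Compute binarized local and long-range FCD maps
#'
#' For every gray-matter voxel v, counts the gray voxels u != v whose
#' Pearson correlation with v strictly exceeds `r_threshold`, split by
#' Euclidean world distance: at most `radius_mm` (inclusive) contributes to
#' local FCD, greater than `radius_mm` to long-range FCD. Degree of the
#' undirected binary graph obtained by thresholding the correlation matrix;
#' zero-variance voxel series contribute no edges but stay in the mask with
#' count 0. Correlations are streamed in voxel blocks so the full matrix is
#' never materialized.
#'
#' @param run a preprocessed [bold_run()].
#' @param gray logical gray-matter mask array.
#' @param params an [fcd_params()].
#' @param block_size voxels per correlation block (memory/speed trade-off).
#' @return list(local = raw-count [fcd_map()], long_range = raw-count
#'   [fcd_map()]).
#' @export
compute_fcd <- function(run, gray, params = fcd_params(), block_size = 2048L) {
  tt <- n_timepoints(run)
  if (tt < 3L) stop("need at least 3 timepoints to correlate")
  idx <- which(gray)
  if (!length(idx)) stop("gray-matter mask is empty")
  d <- run$geometry$dims
  m <- matrix(run$data, prod(d), tt)[idx, , drop = FALSE]
  if (!all(is.finite(m))) stop("run contains non-finite values")
  x <- standardize_rows(m)
  nz <- length(attr(x, "zero_variance"))
  if (nz > 0)
    message(nz, " zero-variance voxel series contribute no edges")
  co <- world_coords_of(run$geometry, idx)
  rr <- rowSums(co^2)
  n <- length(idx)
  r2 <- params$radius_mm^2 + 1e-9
  loc <- integer(n)
  lng <- integer(n)
  for (b0 in seq.int(1L, n, by = block_size)) {
    b <- b0:min(b0 + block_size - 1L, n)
    cb <- x %*% t(x[b, , drop = FALSE])            # n x |b| correlations
    d2 <- outer(rr, rr[b], "+") - 2 * co %*% t(co[b, , drop = FALSE])
    edge <- cb > params$r_threshold
    self <- d2 < 1e-9
    loc[b] <- colSums(edge & !self & d2 <= r2)
    lng[b] <- colSums(edge & d2 > r2)
  }
  to_map <- function(v, kind) {
    arr <- array(0, d)
    arr[idx] <- v
    fcd_map(arr, kind, params, gray, "raw_count")
  }
  list(local = to_map(loc, "local"), long_range = to_map(lng, "long_range"))
}

#' Brute-force FCD reference
#'
#' Materializes the full voxel-by-voxel correlation matrix and the full
#' distance matrix, thresholds and partitions them directly. Exact integer
#' agreement with [compute_fcd()] is the contract; intended for small
#' instances and testing.
#'
#' @inheritParams compute_fcd
#' @param max_voxels refuse instances larger than this (default 5000).
#' @return list(local, long_range) of raw-count [fcd_map()]s.
#' @export
brute_force_fcd <- function(run, gray, params = fcd_params(),
                            max_voxels = 5000L) {
  idx <- which(gray)
  n <- length(idx)
  if (n > max_voxels) stop("instance too large for the brute-force path (",
                           n, " > ", max_voxels, " voxels)")
  if (n_timepoints(run) < 3L) stop("need at least 3 timepoints to correlate")
  d <- run$geometry$dims
  y <- t(matrix(run$data, prod(d), n_timepoints(run))[idx, , drop = FALSE])
  r <- suppressWarnings(stats::cor(y))
  r[!is.finite(r)] <- 0  # zero-variance voxels: no edges
  diag(r) <- 0
  dm <- as.matrix(stats::dist(world_coords_of(run$geometry, idx)))
  adj <- r > params$r_threshold
  near <- dm <= params$radius_mm + 1e-9 & dm > 0
  to_map <- function(v, kind) {
    arr <- array(0, d)
    arr[idx] <- v
    fcd_map(arr, kind, params, gray, "raw_count")
  }
  list(local = to_map(rowSums(adj & near), "local"),
       long_range = to_map(rowSums(adj & !near & dm > 0), "long_range"))
}

#' Normalize a raw FCD map to Z scores
#'
#' Divides the raw degree counts by their mean over the gray-matter mask,
#' then standardizes to Z scores over the mask (population SD, divide by
#' N). Outside-mask voxels are set to 0.
#'
#' @param map a raw-count [fcd_map()].
#' @param gray logical gray-matter mask (defaults to the map's own mask).
#' @return A `normalized`-stage [fcd_map()] with within-mask mean 0, SD 1.
#' @export
normalize_fcd <- function(map, gray = map$mask) {
  stopifnot(map$stage == "raw_count")
  v <- map$values[gray]
  mu <- mean(v)
  if (mu <= 0) stop("no connections above threshold: raw FCD map is all zero")
  v <- v / mu
  sdp <- sqrt(mean((v - mean(v))^2))
  if (sdp <= 0) stop("degenerate FCD map: zero variance over the mask")
  z <- (v - mean(v)) / sdp
  arr <- array(0, dim(map$values))
  arr[gray] <- z
  fcd_map(arr, map$kind, map$params, gray, "normalized")
}

#' Smooth a normalized FCD map with a Gaussian kernel
#'
#' Convolution with a 3D Gaussian of the given FWHM (sigma =
#' FWHM / (2 sqrt(2 ln 2)) per axis, converted to voxel units). Smoothing is
#' mask-renormalized: map*mask and mask are convolved separately and
#' divided, so in-mask values are not diluted toward zero at the mask edge;
#' outside-mask voxels stay 0.
#'
#' @param map a `normalized`-stage [fcd_map()].
#' @param fwhm_mm kernel FWHM in mm (default the map's own parameter).
#' @param geometry a [grid_geometry()] supplying voxel sizes.
#' @return A `smoothed`-stage [fcd_map()].
#' @export
smooth_map <- function(map, fwhm_mm = map$params$fwhm_mm, geometry) {
  stopifnot(fwhm_mm >= 0)
  sig <- fwhm_to_sigma(fwhm_mm) / geometry$voxel_size_mm
  msk <- map$mask * 1
  if (all(sig <= 1e-6)) {
    return(fcd_map(map$values * msk, map$kind, map$params, map$mask,
                   "smoothed"))
  }
  num <- gauss_smooth3d(map$values * msk, sig)
  den <- gauss_smooth3d(msk, sig)
  out <- array(0, dim(map$values))
  inm <- which(map$mask & den > 0)
  out[inm] <- num[inm] / den[inm]
  fcd_map(out, map$kind, map$params, map$mask, "smoothed")
}

#' Full per-subject FCD chain: count, normalize, smooth
#'
#' @param run a preprocessed [bold_run()].
#' @param gray logical gray-matter mask.
#' @param params an [fcd_params()].
#' @return list(local, long_range) of smoothed [fcd_map()]s, with the raw
#'   and normalized stages attached as attributes `raw` and `normalized`.
#' @export
subject_fcd <- function(run, gray, params = fcd_params()) {
  raw <- compute_fcd(run, gray, params)
  out <- lapply(raw, function(m) {
    nm <- normalize_fcd(m, gray)
    sm <- smooth_map(nm, params$fwhm_mm, run$geometry)
    attr(sm, "raw") <- m
    attr(sm, "normalized") <- nm
    sm
  })
  names(out) <- names(raw)
  out
}
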