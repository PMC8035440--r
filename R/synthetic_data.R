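#' Specification of a synthetic two-group resting-state cohort
#'
#' Captures everything needed to generate a reproducible two-group fMRI
#' cohort with planted connectivity structure: the grid, run length and TR,
#' group sizes, local correlated hubs and long-range correlated region
#' pairs per group, the frequency band of the planted signal, and the
#' noise/motion model.
#'
#' A local hub is `list(center = c(i, j, k), radius_mm = r, share = s)`:
#' every gray-matter voxel within `r` mm of the centre receives a common
#' band-limited source carrying a fraction `share` of its variance, so the
#' expected Pearson correlation between two co-hub voxels equals `share`.
#' A long-range pair is `list(region_a = <n x 3 ijk matrix>,
#' region_b = <m x 3 ijk matrix>, share = s)`: all voxels of both regions
#' share one source the same way.
#'
#' @param geometry a [grid_geometry()]; default 20x20x20 at 3 mm.
#' @param n_timepoints volumes per run (default 240).
#' @param tr_s repetition time in seconds (default 2).
#' @param n_per_group subjects per group (default 32).
#' @param local_hubs named list with elements `A` and `B`, each a list of hubs.
#' @param long_pairs named list with elements `A` and `B`, each a list of pairs.
#' @param signal_band_hz frequency band of the planted sources (default
#'   0.01-0.1 Hz, the band the preprocessing retains).
#' @param ar1_coeff lag-1 autoregressive coefficient of the voxel noise.
#' @param noise_sd scaling of the noise component relative to unit-variance
#'   sources; 1 preserves the share = expected-correlation calibration.
#' @param motion_severity non-negative scaling of motion drift amplitude;
#'   0 gives all-zero traces, the default 1 stays well under the 1.5 mm
#'   exclusion limit, 10 violates it with high probability.
#' @param seed integer master seed; every subject derives its own stream.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(geometry = grid_geometry(c(20, 20, 20)),
                           n_timepoints = 240L, tr_s = 2,
                           n_per_group = 32L,
                           local_hubs = list(A = list(), B = list()),
                           long_pairs = list(A = list(), B = list()),
                           signal_band_hz = c(0.01, 0.1),
                           ar1_coeff = 0.3, noise_sd = 1,
                           motion_severity = 1, seed = 1L) {
  stopifnot(inherits(geometry, "grid_geometry"),
            n_timepoints >= 1, tr_s > 0, n_per_group >= 1,
            is.list(local_hubs), is.list(long_pairs),
            length(signal_band_hz) == 2L,
            signal_band_hz[1] > 0, signal_band_hz[1] < signal_band_hz[2],
            ar1_coeff >= 0, ar1_coeff < 1, noise_sd >= 0,
            motion_severity >= 0)
  nyq <- 1 / (2 * tr_s)
  if (signal_band_hz[2] > nyq)
    stop("signal band upper edge ", signal_band_hz[2],
         " Hz exceeds Nyquist frequency ", nyq, " Hz")
  for (g in c("A", "B")) {
    for (h in local_hubs[[g]]) stopifnot(h$radius_mm > 0,
                                         h$share >= 0, h$share <= 1)
    for (p in long_pairs[[g]]) stopifnot(p$share >= 0, p$share <= 1)
  }
  structure(list(geometry = geometry, n_timepoints = as.integer(n_timepoints),
                 tr_s = tr_s, n_per_group = as.integer(n_per_group),
                 local_hubs = local_hubs, long_pairs = long_pairs,
                 signal_band_hz = signal_band_hz, ar1_coeff = ar1_coeff,
                 noise_sd = noise_sd, motion_severity = motion_severity,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default study-scale cohort specification
#'
#' A ready-made [synthetic_spec()] mirroring the study design the pipeline
#' targets: two groups of 32 subjects, 240 volumes at TR 2 s on a 3 mm grid,
#' with one local hub (6 mm radius) and one long-range region pair planted
#' in group A only.
#'
#' @param geometry grid (default 20x20x20 at 3 mm).
#' @param n_per_group subjects per group (default 32).
#' @param hub_share,pair_share variance share of the planted sources in
#'   group A (default 0.8 each); group B receives none.
#' @param seed master seed.
#' @inheritParams synthetic_spec
#' @return A `synthetic_spec`.
#' @export
default_study_spec <- function(geometry = grid_geometry(c(20, 20, 20)),
                               n_per_group = 32L, hub_share = 0.8,
                               pair_share = 0.8, motion_severity = 1,
                               seed = 1L) {
  masks <- make_tissue_masks(geometry)
  # place planted structure relative to the gray-matter core radius so the
  # same spec scales across grids: hub on +x, pair regions on -x and -y,
  # separated by more than the 6 mm local sphere on grids of ~16^3 and up
  g_r <- 0.45 * min(geometry$dims * geometry$voxel_size_mm) -
    2 * max(geometry$voxel_size_mm)
  hub_center <- nearest_gray_voxel(geometry, masks, c(0.5 * g_r, 0, 0))
  reg_a <- gray_sphere(geometry, masks, c(-0.6 * g_r, 0, 0), 3.5)
  reg_b <- gray_sphere(geometry, masks, c(0, -0.6 * g_r, 0), 3.5)
  synthetic_spec(
    geometry = geometry, n_per_group = n_per_group,
    local_hubs = list(
      A = list(list(center = hub_center, radius_mm = 6, share = hub_share)),
      B = list()),
    long_pairs = list(
      A = list(list(region_a = reg_a, region_b = reg_b, share = pair_share)),
      B = list()),
    motion_severity = motion_severity, seed = seed)
}

#' Gray-matter voxels within a sphere
#'
#' @param geometry a [grid_geometry()].
#' @param masks a `tissue_masks` object.
#' @param center_world world-mm centre of the sphere.
#' @param radius_mm sphere radius.
#' @return n x 3 matrix of 1-based voxel indices.
#' @export
gray_sphere <- function(geometry, masks, center_world, radius_mm) {
  idx <- which(masks$gray)
  w <- world_coords_of(geometry, idx)
  d <- sqrt(rowSums(sweep(w, 2L, as.numeric(center_world))^2))
  sel <- idx[d <= radius_mm]
  if (!length(sel)) stop("no gray-matter voxel within ", radius_mm,
                         " mm of the requested centre")
  arrayInd(sel, geometry$dims)
}

# Gray voxel (ijk) closest to a world coordinate.
nearest_gray_voxel <- function(geometry, masks, center_world) {
  idx <- which(masks$gray)
  w <- world_coords_of(geometry, idx)
  d <- rowSums(sweep(w, 2L, as.numeric(center_world))^2)
  arrayInd(idx[which.min(d)], geometry$dims)[1, ]
}

# Band-limited unit-variance Gaussian source: white noise restricted to
# [low, high] Hz in the frequency domain, scaled by the theoretical
# power fraction so the stationary variance is 1.
band_limited_source <- function(n, tr_s, band_hz) {
  z <- stats::rnorm(n)
  g <- band_gain(n, tr_s, band_hz[1], band_hz[2], taper = FALSE)
  pw <- mean(g^2)
  if (pw <= 0) stop("signal band contains no frequency bin at this run length")
  x <- Re(stats::fft(stats::fft(z) * g, inverse = TRUE)) / n
  x / sqrt(pw)
}

# Frequency-domain gain vector of length n for a [low, high] Hz band.
# With taper = TRUE the edges get a raised-cosine ramp one bin wide
# (zero-phase: the gain is real and even in frequency).
band_gain <- function(n, tr_s, low_hz, high_hz, taper = TRUE) {
  freq <- (seq_len(n) - 1) / (n * tr_s)
  f <- pmin(freq, 1 / tr_s - freq)  # fold onto [0, Nyquist]
  g <- numeric(n)
  if (taper) {
    tw <- 1 / (n * tr_s)
    up <- f > low_hz - tw & f < low_hz
    dn <- f > high_hz & f < high_hz + tw
    g[f >= low_hz & f <= high_hz] <- 1
    g[up] <- 0.5 * (1 + cos(pi * (low_hz - f[up]) / tw))
    g[dn] <- 0.5 * (1 + cos(pi * (f[dn] - high_hz) / tw))
  } else {
    g[f >= low_hz & f <= high_hz] <- 1
  }
  g
}

# Linear (column-major) indices of an ijk matrix.
ijk_to_linear <- function(ijk, dims) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  ijk[, 1] + (ijk[, 2] - 1L) * dims[1] + (ijk[, 3] - 1L) * dims[1] * dims[2]
}

# Validate that all planted voxels of a group lie inside gray matter; return
# list(members = list of linear index vectors, shares = numeric) per source.
planted_sources <- function(spec, group, masks) {
  geom <- spec$geometry
  out <- list()
  for (h in spec$local_hubs[[group]]) {
    mem <- ijk_to_linear(gray_sphere(geom, masks,
                                     voxel_to_world(geom, matrix(h$center, 1L)),
                                     h$radius_mm), geom$dims)
    ctr <- ijk_to_linear(matrix(h$center, 1L), geom$dims)
    if (!masks$gray[ctr])
      stop("local hub centre (", paste(h$center, collapse = ","),
           ") lies outside the gray-matter mask")
    out[[length(out) + 1L]] <- list(members = mem, share = h$share)
  }
  for (p in spec$long_pairs[[group]]) {
    lin <- c(ijk_to_linear(p$region_a, geom$dims),
             ijk_to_linear(p$region_b, geom$dims))
    if (!all(masks$gray[lin]))
      stop("long-range pair region contains voxels outside the gray-matter mask")
    out[[length(out) + 1L]] <- list(members = unique(lin), share = p$share)
  }
  out
}

#' Generate one synthetic subject
#'
#' Simulates a 4D BOLD run plus a motion trace. Every voxel carries
#' AR(1)-plus-white noise; voxels belonging to a planted hub or long-range
#' pair are mixed as `sqrt(share) * source + sqrt(1 - share) * noise_sd *
#' noise` with unit-variance components, so at `noise_sd = 1` the expected
#' correlation between two voxels sharing a source equals `share`. Sources
#' are band-limited to `signal_band_hz` so planted correlations survive the
#' pipeline's bandpass filter. Deterministic given `(seed, group,
#' subject_index)`.
#'
#' @param spec a [synthetic_spec()].
#' @param group `"A"` or `"B"`.
#' @param subject_index 1-based index within the group.
#' @return A `subject_data` object: `bold` ([bold_run()]), `motion`
#'   ([motion_params()]), `group`, `subject_id`.
#' @export
generate_subject <- function(spec, group, subject_index) {
  stopifnot(inherits(spec, "synthetic_spec"), group %in% c("A", "B"),
            subject_index >= 1, subject_index <= spec$n_per_group)
  geom <- spec$geometry
  masks <- make_tissue_masks(geom)
  sources <- planted_sources(spec, group, masks)
  tt <- spec$n_timepoints
  nvox <- prod(geom$dims)
  gcode <- match(group, c("A", "B"))
  sseed <- mix_seed(spec$seed, gcode, subject_index)
  dat <- with_seed(sseed, {
    # AR(1) + white voxel noise, theoretical unit variance.
    # voxels x time orientation keeps the AR recursion column-contiguous.
    phi <- spec$ar1_coeff
    ar <- matrix(stats::rnorm(tt * nvox), nvox, tt)
    if (phi > 0) {
      ar[, 1] <- ar[, 1] / sqrt(1 - phi^2)
      for (t in 2:tt) ar[, t] <- phi * ar[, t - 1L] + ar[, t]
      ar <- ar * sqrt(1 - phi^2)
    }
    eps <- (ar + matrix(stats::rnorm(tt * nvox), nvox, tt)) / sqrt(2)
    v <- spec$noise_sd * eps
    for (s in sources) {
      src <- band_limited_source(tt, spec$tr_s, spec$signal_band_hz)
      v[s$members, ] <- rep(sqrt(s$share) * src, each = length(s$members)) +
        sqrt(1 - s$share) * spec$noise_sd * eps[s$members, , drop = FALSE]
    }
    1000 + 20 * v
  })
  bold <- bold_run(array(dat, c(geom$dims, tt)), geom, spec$tr_s)
  motion <- generate_motion(spec, seed_offset = mix_seed(sseed, 99L))
  structure(list(bold = bold, motion = motion, group = group,
                 subject_id = sprintf("sub-%s%02d", group, subject_index)),
            class = "subject_data")
}

#' Generate a smooth random-walk motion trace
#'
#' Six columns (translations x,y,z in mm, rotations x,y,z in degrees), one
#' row per timepoint. Each column is a smoothed Gaussian random walk scaled
#' by `motion_severity^1.5`, anchored at zero at the first timepoint. The
#' maximum absolute excursion grows monotonically with `motion_severity`;
#' severity 0 yields an all-zero trace and severity around 10 exceeds the
#' 1.5 mm exclusion limit with high probability.
#'
#' @param spec a [synthetic_spec()].
#' @param seed_offset integer seed for this trace.
#' @return A [motion_params()] object with `n_timepoints` rows.
#' @export
generate_motion <- function(spec, seed_offset = 0L) {
  tt <- spec$n_timepoints
  stopifnot(tt >= 1)
  sev <- spec$motion_severity
  if (sev == 0) return(motion_params(matrix(0, tt, 6L)))
  m <- with_seed(mix_seed(seed_offset), {
    amp <- 0.008 * sev^1.5
    steps <- matrix(stats::rnorm(tt * 6L), tt, 6L)
    if (tt >= 5L) {
      steps <- apply(steps, 2L, function(x)
        as.numeric(stats::filter(x, rep(1 / 5, 5), circular = TRUE)) * sqrt(5))
    }
    tr <- apply(steps, 2L, cumsum) * amp
    sweep(matrix(tr, tt, 6L), 2L, matrix(tr, tt, 6L)[1L, ])
  })
  motion_params(m)
}

#' Generate a full two-group cohort with tissue masks
#'
#' @param spec a [synthetic_spec()].
#' @return A `cohort` object: `subjects` (list of `subject_data`, group A
#'   then group B), `masks` (`tissue_masks`), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  masks <- make_tissue_masks(spec$geometry)
  subjects <- list()
  for (g in c("A", "B"))
    for (i in seq_len(spec$n_per_group))
      subjects[[length(subjects) + 1L]] <- generate_subject(spec, g, i)
  structure(list(subjects = subjects, masks = masks, spec = spec),
            class = "cohort")
}
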