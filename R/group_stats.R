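#' Voxel-wise t-statistic map
#'
#' @param t_values 3D array of t statistics (0 outside mask).
#' @param df degrees of freedom.
#' @param mask logical gray mask.
#' @param contrast description string.
#' @return A `stat_map` object.
#' @export
stat_map <- function(t_values, df, mask, contrast) {
  structure(list(t_values = t_values, df = df, mask = mask,
                 contrast = contrast), class = "stat_map")
}

map_values <- function(m) if (inherits(m, "fcd_map")) m$values else m

# Stack a list of maps into an n_mask_voxels x n_subjects matrix.
stack_maps <- function(maps, mask) {
  idx <- which(mask)
  matrix(vapply(maps, function(m) map_values(m)[idx], numeric(length(idx))),
         nrow = length(idx))
}

#' One-sample t-map within a group
#'
#' Per-voxel t = mean / (SD / sqrt(n)) with sample SD; df = n - 1.
#' Zero-variance voxels get t = 0 and are counted in the
#' `n_zero_variance` attribute.
#'
#' @param maps list of smoothed [fcd_map()]s (or plain 3D arrays).
#' @param mask logical gray mask.
#' @return A [stat_map()].
#' @export
one_sample_t <- function(maps, mask) {
  n <- length(maps)
  if (n < 2L) stop("need at least 2 subjects for a one-sample t test")
  v <- stack_maps(maps, mask)
  mu <- rowMeans(v)
  s <- sqrt(rowSums((v - mu)^2) / (n - 1))
  tval <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
  arr <- array(0, dim(map_values(maps[[1]])))
  arr[which(mask)] <- tval
  out <- stat_map(arr, n - 1L, mask, "one-sample")
  attr(out, "n_zero_variance") <- sum(s <= 0)
  out
}

#' Two-sample pooled-variance t-map (group A minus group B)
#'
#' Student's t with pooled variance; df = nA + nB - 2. Voxels with zero
#' pooled variance get t = 0 and are flagged.
#'
#' @param maps_a,maps_b lists of smoothed [fcd_map()]s per group.
#' @param mask logical gray mask.
#' @return A [stat_map()].
#' @export
two_sample_t <- function(maps_a, maps_b, mask) {
  na <- length(maps_a); nb <- length(maps_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 subjects")
  va <- stack_maps(maps_a, mask)
  vb <- stack_maps(maps_b, mask)
  mua <- rowMeans(va); mub <- rowMeans(vb)
  ssa <- rowSums((va - mua)^2)
  ssb <- rowSums((vb - mub)^2)
  sp2 <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tval <- ifelse(se > 0, (mua - mub) / se, 0)
  arr <- array(0, dim(map_values(maps_a[[1]])))
  arr[which(mask)] <- tval
  out <- stat_map(arr, na + nb - 2L, mask, "two-sample A-B")
  attr(out, "n_zero_variance") <- sum(se <= 0)
  out
}

#' Cluster-level multiple-comparison correction parameters
#'
#' @param voxel_p voxel-level p threshold (default .01).
#' @param cluster_p cluster-level family-wise p (default .05).
#' @param two_tailed two-tailed voxel thresholding (default TRUE).
#' @param n_simulations Monte-Carlo iterations (default 1000).
#' @param fwhm_mm smoothness of the simulated null noise in mm (default 6,
#'   the applied smoothing kernel).
#' @param connectivity cluster connectivity: 6, 18 or 26 (default 26).
#' @param seed RNG seed for the simulation.
#' @return A `correction_params` object.
#' @export
correction_params <- function(voxel_p = 0.01, cluster_p = 0.05,
                              two_tailed = TRUE, n_simulations = 1000L,
                              fwhm_mm = 6, connectivity = 26L, seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1,
            n_simulations >= 1, all(fwhm_mm >= 0),
            length(fwhm_mm) %in% c(1L, 3L),
            connectivity %in% c(6L, 18L, 26L))
  structure(list(voxel_p = voxel_p, cluster_p = cluster_p,
                 two_tailed = two_tailed,
                 n_simulations = as.integer(n_simulations),
                 fwhm_mm = fwhm_mm, connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "correction_params")
}

# Lag-1 autocorrelation along one axis of white noise smoothed with the
# package's discrete Gaussian kernel of standard deviation sigma (voxels).
discrete_lag1_corr <- function(sigma) {
  if (sigma <= 1e-3) return(0)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- stats::dnorm(seq(-h, h), sd = sigma)
  w <- w / sum(w)
  sum(w[-1] * w[-length(w)]) / sum(w^2)
}

#' Estimate the effective smoothness of residual maps
#'
#' Estimates, per axis, the FWHM of the Gaussian kernel whose discrete
#' application to white noise reproduces the lag-1 spatial autocorrelation
#' observed in the maps' residuals about their group means. This is the
#' smoothness that should enter the Monte-Carlo null: FCD maps carry
#' intrinsic spatial correlation beyond the applied smoothing kernel
#' (neighbouring voxels share graph edges), so assuming the applied FWHM
#' understates chance cluster sizes.
#'
#' @param maps list of smoothed maps ([fcd_map()] or arrays), all subjects.
#' @param mask logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @param groups optional character vector of group labels per map; when
#'   given, each group's mean map is removed before estimation so planted
#'   or real effects do not masquerade as smoothness.
#' @return numeric length-3 FWHM in mm per axis.
#' @export
estimate_smoothness <- function(maps, mask, geometry, groups = NULL) {
  d <- geometry$dims
  idx <- which(mask)
  v <- vapply(maps, function(m) map_values(m)[idx], numeric(length(idx)))
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      sel <- groups == g
      v[, sel] <- v[, sel] - rowMeans(v[, sel, drop = FALSE])
    }
  } else {
    v <- v - rowMeans(v)
  }
  ijk <- arrayInd(idx, d)
  lin <- function(m) m[, 1] + (m[, 2] - 1L) * d[1] + (m[, 3] - 1L) * d[1] * d[2]
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  fwhm <- numeric(3)
  for (ax in 1:3) {
    sh <- c(0L, 0L, 0L)
    sh[ax] <- 1L
    nb <- sweep(ijk, 2L, sh, "+")
    ok <- nb[, ax] <= d[ax]
    j <- pos[lin(nb[ok, , drop = FALSE])]
    keep <- j > 0L
    i <- which(ok)[keep]
    j <- j[keep]
    num <- 0; den <- 0
    for (s in seq_len(ncol(v))) {
      e <- v[, s]
      num <- num + stats::var(e[j] - e[i])
      den <- den + stats::var(e)
    }
    rho <- 1 - num / (2 * den)
    sig <- if (rho <= 0) 1e-3 else if (rho >= discrete_lag1_corr(10)) 10 else
      stats::uniroot(function(s) discrete_lag1_corr(s) - rho,
                     c(1e-3, 10), tol = 1e-4)$root
    fwhm[ax] <- sig * 2 * sqrt(2 * log(2)) * geometry$voxel_size_mm[ax]
  }
  fwhm
}

# Package-level cache of Monte-Carlo extent thresholds, keyed on every
# parameter that affects the null distribution.
.ext_cache <- new.env(parent = emptyenv())

cached_extent_threshold <- function(mask, geometry, params, fwhm_mm,
                                    n_a = NULL, n_b = NULL) {
  fwhm_mm <- round(fwhm_mm / 0.5) * 0.5
  p <- params
  p$fwhm_mm <- fwhm_mm
  key <- paste(c(geometry$dims, sum(mask), signif(geometry$voxel_size_mm, 6),
                 p$voxel_p, p$cluster_p, p$two_tailed, p$n_simulations,
                 fwhm_mm, p$connectivity, p$seed, n_a, n_b), collapse = "|")
  if (is.null(.ext_cache[[key]]))
    .ext_cache[[key]] <- cluster_extent_threshold(mask, geometry, p, n_a, n_b)
  .ext_cache[[key]]
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Estimates the null distribution of the maximum suprathreshold cluster
#' size in smoothed noise and returns the smallest extent k such that the
#' probability of a chance cluster of size >= k is at most `cluster_p`.
#' Deterministic given the seed in `params`.
#'
#' Two null models are available. With `n_a`/`n_b` supplied (the default
#' path used by the pipeline), each iteration simulates `n_a + n_b`
#' independent smoothed Gaussian noise volumes, computes the two-sample
#' pooled t-map, and thresholds it at the voxel-level t critical value for
#' `n_a + n_b - 2` df -- a parametric Monte Carlo of the actual group
#' statistic. Without group sizes, each iteration simulates a single
#' smoothed Gaussian field standardized within the mask and thresholds at
#' the z cutoff (the classic AlphaSim null); this is slightly
#' anticonservative for low-df t contrasts.
#'
#' @param mask logical analysis mask.
#' @param geometry a [grid_geometry()].
#' @param params a [correction_params()].
#' @param n_a,n_b group sizes for the two-sample t null model; both NULL
#'   selects the single-field Gaussian null.
#' @return integer minimum cluster size in voxels.
#' @export
cluster_extent_threshold <- function(mask, geometry, params,
                                     n_a = NULL, n_b = NULL) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  if (params$n_simulations < 100L)
    warning("fewer than 100 Monte-Carlo iterations; extent threshold is noisy")
  d <- geometry$dims
  tstat_null <- !is.null(n_a) && !is.null(n_b)
  cut <- if (tstat_null) {
    df <- n_a + n_b - 2
    if (params$two_tailed) stats::qt(1 - params$voxel_p / 2, df)
    else stats::qt(1 - params$voxel_p, df)
  } else {
    if (params$two_tailed) stats::qnorm(1 - params$voxel_p / 2)
    else stats::qnorm(1 - params$voxel_p)
  }
  sig <- fwhm_to_sigma(params$fwhm_mm) / geometry$voxel_size_mm
  msk <- mask * 1
  do_smooth <- any(params$fwhm_mm > 0)
  den <- if (do_smooth) gauss_smooth3d(msk, sig) else msk
  kmats <- if (do_smooth) smooth_kernels(d, sig) else NULL
  nv <- length(idx)
  vols_per_sim <- if (tstat_null) n_a + n_b else 1L
  # batch several simulations through one stacked convolution pass
  sims_per_chunk <- max(1L, min(params$n_simulations,
                                as.integer(200 / vols_per_sim)))
  sim_fields <- function(nvol) {
    # noise outside the mask is multiplied by zero before smoothing, so
    # only in-mask voxels need draws; all volumes share one stacked pass
    big <- matrix(0, prod(d), nvol)
    big[idx, ] <- stats::rnorm(nv * nvol)
    if (do_smooth) {
      sm <- gauss_smooth_stack(array(big, c(d, nvol)), sig, kmats)
      matrix(sm, prod(d), nvol)[idx, , drop = FALSE] / den[idx]
    } else big[idx, , drop = FALSE]
  }
  max_cluster <- function(z) {
    za <- array(0, d)
    za[idx] <- z
    sizes <- lengths(label_components(za > cut, params$connectivity))
    if (params$two_tailed)
      sizes <- c(sizes, lengths(label_components(za < -cut,
                                                 params$connectivity)))
    if (length(sizes)) max(sizes) else 0L
  }
  maxsize <- with_seed(params$seed, {
    out <- numeric(params$n_simulations)
    done <- 0L
    while (done < params$n_simulations) {
      ns <- min(sims_per_chunk, params$n_simulations - done)
      v <- sim_fields(ns * vols_per_sim)
      for (k in seq_len(ns)) {
        if (tstat_null) {
          va <- v[, (k - 1L) * vols_per_sim + seq_len(n_a), drop = FALSE]
          vb <- v[, (k - 1L) * vols_per_sim + n_a + seq_len(n_b),
                  drop = FALSE]
          mua <- rowMeans(va); mub <- rowMeans(vb)
          sp2 <- (rowSums((va - mua)^2) + rowSums((vb - mub)^2)) /
            (n_a + n_b - 2)
          se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
          z <- ifelse(se > 0, (mua - mub) / se, 0)
        } else {
          z <- v[, k]
          z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
        }
        out[done + k] <- max_cluster(z)
      }
      done <- done + ns
    }
    out
  })
  kmax <- max(maxsize)
  if (kmax == 0) return(1L)
  for (k in seq_len(kmax)) {
    if (mean(maxsize >= k) <= params$cluster_p) return(as.integer(k))
  }
  as.integer(kmax + 1L)
}

#' Extract significant clusters from a t-map
#'
#' Thresholds |t| at the two-tailed voxel-level critical value for the
#' map's df, forms connected components separately for positive and
#' negative voxels, discards components smaller than the extent threshold,
#' and returns a table sorted by descending |peak t|. Peak coordinates are
#' reported at the maximum-|t| member voxel (ties broken by lowest linear
#' index) mapped through the affine.
#'
#' @param stat a [stat_map()].
#' @param params a [correction_params()].
#' @param extent_threshold minimum cluster size in voxels (>= 1).
#' @param geometry a [grid_geometry()].
#' @return A `cluster_table`: data.frame with columns `cluster_id`, `sign`,
#'   `size_voxels`, `peak_t`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, plus a
#'   `voxels` attribute (list of linear-index vectors, same order).
#' @export
extract_clusters <- function(stat, params, extent_threshold, geometry) {
  stopifnot(extent_threshold >= 1)
  tcut <- if (params$two_tailed) stats::qt(1 - params$voxel_p / 2, stat$df)
          else stats::qt(1 - params$voxel_p, stat$df)
  tv <- stat$t_values
  comps <- list()
  signs <- character(0)
  pos <- label_components(tv > tcut, params$connectivity)
  comps <- c(comps, pos)
  signs <- c(signs, rep("positive", length(pos)))
  if (params$two_tailed) {
    neg <- label_components(tv < -tcut, params$connectivity)
    comps <- c(comps, neg)
    signs <- c(signs, rep("negative", length(neg)))
  }
  keep <- lengths(comps) >= extent_threshold
  comps <- comps[keep]
  signs <- signs[keep]
  rows <- lapply(seq_along(comps), function(i) {
    vx <- sort(comps[[i]])
    at <- abs(tv[vx])
    pk <- vx[which.max(at)]  # which.max returns the first (lowest index) tie
    pw <- world_coords_of(geometry, pk)
    data.frame(cluster_id = NA_character_, sign = signs[i],
               size_voxels = length(vx), peak_t = tv[pk],
               peak_x_mm = pw[1], peak_y_mm = pw[2], peak_z_mm = pw[3],
               stringsAsFactors = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(0), sign = character(0),
               size_voxels = integer(0), peak_t = numeric(0),
               peak_x_mm = numeric(0), peak_y_mm = numeric(0),
               peak_z_mm = numeric(0), stringsAsFactors = FALSE)
  ord <- order(-abs(tab$peak_t))
  tab <- tab[ord, , drop = FALSE]
  comps <- comps[ord]
  if (nrow(tab)) tab$cluster_id <- sprintf("cl%02d", seq_len(nrow(tab)))
  rownames(tab) <- NULL
  attr(tab, "voxels") <- lapply(comps, sort)
  attr(tab, "extent_threshold") <- as.integer(extent_threshold)
  attr(tab, "df") <- stat$df
  class(tab) <- c("cluster_table", "data.frame")
  tab
}
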