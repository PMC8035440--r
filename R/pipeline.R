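#' Run the full FCD analysis on an in-memory cohort
#'
#' End-to-end: temporal preprocessing with motion-based exclusion, local and
#' long-range FCD mapping (count, normalize, smooth), within-group
#' one-sample t-maps, the between-group two-sample t-map, Monte-Carlo
#' cluster-extent correction, cluster extraction, and ROC analysis of each
#' surviving cluster's per-subject mean FCD.
#'
#' ROC caveat: clusters are selected by the same contrast the ROC then
#' evaluates, so the reported AUCs are optimistically biased; this mirrors
#' the standard (circular) region-of-interest practice and should be read
#' as descriptive, not as out-of-sample accuracy.
#'
#' @param cohort a [generate_cohort()] result (or a compatible list with
#'   `subjects`, `masks`, `spec`).
#' @param fcd an [fcd_params()].
#' @param correction a [correction_params()].
#' @param n_drop initial volumes to discard (default 10).
#' @param trans_limit_mm,rot_limit_deg motion exclusion limits (1.5/1.5).
#' @param band bandpass edges in Hz (default c(0.01, 0.1)).
#' @param extent_threshold optional precomputed minimum cluster size
#'   (scalar, or a named list with elements `local` and `long_range`); when
#'   NULL it is computed by [cluster_extent_threshold()].
#' @param smoothness `"estimate"` (default) derives the smoothness entering
#'   the Monte-Carlo null from the maps' residuals via
#'   [estimate_smoothness()], per FCD kind; `"applied"` uses the
#'   correction parameters' `fwhm_mm` (the applied kernel), which
#'   understates the intrinsic smoothness of local-FCD maps and is kept
#'   for comparison only.
#' @param ci_method ROC confidence-interval method.
#' @return A list with elements `excluded` (subject ids), `kept_ids`,
#'   `groups`, `maps` (per kind: per-subject smoothed maps split by group),
#'   `stats` (per kind: one-sample A and B, two-sample), `extent_threshold`,
#'   `clusters` (per kind: [extract_clusters()] table), `roc` (per kind:
#'   list of [roc_auc()] results, one per cluster) and `params`.
#' @export
analyze_cohort <- function(cohort, fcd = fcd_params(),
                           correction = correction_params(),
                           n_drop = 10L, trans_limit_mm = 1.5,
                           rot_limit_deg = 1.5, band = c(0.01, 0.1),
                           extent_threshold = NULL,
                           smoothness = c("estimate", "applied"),
                           ci_method = "delong") {
  smoothness = match.arg(smoothness)
  masks <- cohort$masks
  geom <- cohort$spec$geometry
  excluded <- character(0)
  kept <- list()
  for (s in cohort$subjects) {
    pp <- preprocess_subject(s$bold, s$motion, masks, n_drop,
                             trans_limit_mm, rot_limit_deg, band)
    if (pp$excluded) {
      excluded <- c(excluded, s$subject_id)
    } else {
      kept[[length(kept) + 1L]] <- list(id = s$subject_id, group = s$group,
                                        run = pp$run)
    }
  }
  if (length(kept) < 4L)
    stop("fewer than 4 subjects survive motion exclusion")
  groups <- vapply(kept, `[[`, character(1), "group")
  ids <- vapply(kept, `[[`, character(1), "id")
  if (sum(groups == "A") < 2L || sum(groups == "B") < 2L)
    stop("each group needs at least 2 retained subjects")
  fcd_maps <- lapply(kept, function(k) subject_fcd(k$run, masks$gray, fcd))
  maps <- list()
  stats_out <- list()
  clusters <- list()
  roc <- list()
  smooth_est <- list()
  ext_used <- list()
  for (kind in c("local", "long_range")) {
    mk <- lapply(fcd_maps, `[[`, kind)
    ma <- mk[groups == "A"]
    mb <- mk[groups == "B"]
    maps[[kind]] <- list(A = ma, B = mb)
    stats_out[[kind]] <- list(
      one_sample_A = one_sample_t(ma, masks$gray),
      one_sample_B = one_sample_t(mb, masks$gray),
      two_sample = two_sample_t(ma, mb, masks$gray))
    ext <- extent_threshold
    if (is.list(ext)) ext <- ext[[kind]]
    if (is.null(ext)) {
      fw <- if (smoothness == "estimate") {
        smooth_est[[kind]] <- estimate_smoothness(mk, masks$gray, geom, groups)
        smooth_est[[kind]]
      } else correction$fwhm_mm
      ext <- cached_extent_threshold(masks$gray, geom, correction, fw,
                                     n_a = sum(groups == "A"),
                                     n_b = sum(groups == "B"))
    }
    ext_used[[kind]] <- ext
    ct <- extract_clusters(stats_out[[kind]]$two_sample, correction, ext, geom)
    clusters[[kind]] <- ct
    vx <- attr(ct, "voxels")
    roc[[kind]] <- lapply(seq_along(vx), function(i) {
      cv <- cluster_mean_values(ma, mb, vx[[i]],
                                cluster_id = ct$cluster_id[i])
      roc_auc(cv, ci_method = ci_method, seed = correction$seed)
    })
  }
  list(excluded = excluded, kept_ids = ids, groups = groups, maps = maps,
       stats = stats_out, extent_threshold = ext_used,
       smoothness_fwhm_mm = smooth_est, clusters = clusters, roc = roc,
       params = list(fcd = fcd, correction = correction, n_drop = n_drop,
                     trans_limit_mm = trans_limit_mm,
                     rot_limit_deg = rot_limit_deg, band = band))
}
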