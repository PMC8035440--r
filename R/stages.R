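#' Study configuration
#'
#' Bundles every tunable of the pipeline with the study's default values:
#' 10 dropped volumes, 1.5 mm / 1.5 degree motion limits, 0.01-0.1 Hz band,
#' correlation threshold 0.3, 6 mm sphere radius, 6 mm FWHM, voxel p < .01,
#' cluster p < .05.
#'
#' @param out output directory for [run_pipeline()].
#' @param simulate optional [synthetic_spec()]; when given, the pipeline
#'   generates its cohort instead of reading one from `out/cohort`.
#' @param fcd an [fcd_params()].
#' @param correction a [correction_params()].
#' @param n_drop,trans_limit_mm,rot_limit_deg,band preprocessing settings.
#' @param ci_method,n_boot ROC confidence-interval settings.
#' @param seed global seed (propagated to stochastic stages).
#' @return A `study_config` object.
#' @export
study_config <- function(out, simulate = NULL, fcd = fcd_params(),
                         correction = correction_params(),
                         n_drop = 10L, trans_limit_mm = 1.5,
                         rot_limit_deg = 1.5, band = c(0.01, 0.1),
                         ci_method = "delong", n_boot = 2000L, seed = 1L) {
  correction$seed <- as.integer(seed)
  structure(list(out = out, simulate = simulate, fcd = fcd,
                 correction = correction, n_drop = as.integer(n_drop),
                 trans_limit_mm = trans_limit_mm,
                 rot_limit_deg = rot_limit_deg, band = band,
                 ci_method = ci_method, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Recognized top-level keys: `out`, `seed`, `simulate` (grid dims,
#' voxel_size_mm, n_timepoints, tr_s, n_per_group, hub_share, pair_share,
#' motion_severity), `fcd` (r_threshold, radius_mm, fwhm_mm), `correction`
#' (voxel_p, cluster_p, two_tailed, n_simulations, fwhm_mm, connectivity),
#' `preprocess` (n_drop, trans_limit_mm, rot_limit_deg, band), `roc`
#' (ci_method, n_boot). Missing keys keep the study defaults.
#'
#' @param path YAML file.
#' @param out optional output-directory override.
#' @param seed optional seed override.
#' @return A [study_config()].
#' @export
read_study_config <- function(path, out = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  take <- function(x, nm, def) if (!is.null(x[[nm]])) x[[nm]] else def
  seed <- if (!is.null(seed)) seed else take(y, "seed", 1L)
  sim <- NULL
  if (!is.null(y$simulate)) {
    s <- y$simulate
    geom <- grid_geometry(take(s, "dims", c(20, 20, 20)),
                          take(s, "voxel_size_mm", c(3, 3, 3)))
    sim <- default_study_spec(
      geometry = geom,
      n_per_group = take(s, "n_per_group", 32L),
      hub_share = take(s, "hub_share", 0.8),
      pair_share = take(s, "pair_share", 0.8),
      motion_severity = take(s, "motion_severity", 1),
      seed = seed)
    sim$n_timepoints <- as.integer(take(s, "n_timepoints", 240L))
    sim$tr_s <- take(s, "tr_s", 2)
  }
  f <- y$fcd
  co <- y$correction
  pp <- y$preprocess
  ro <- y$roc
  study_config(
    out = if (!is.null(out)) out else y$out,
    simulate = sim,
    fcd = fcd_params(take(f, "r_threshold", 0.3), take(f, "radius_mm", 6),
                     take(f, "fwhm_mm", 6)),
    correction = correction_params(
      take(co, "voxel_p", 0.01), take(co, "cluster_p", 0.05),
      take(co, "two_tailed", TRUE), take(co, "n_simulations", 1000L),
      take(co, "fwhm_mm", 6), take(co, "connectivity", 26L), seed),
    n_drop = take(pp, "n_drop", 10L),
    trans_limit_mm = take(pp, "trans_limit_mm", 1.5),
    rot_limit_deg = take(pp, "rot_limit_deg", 1.5),
    band = unlist(take(pp, "band", c(0.01, 0.1))),
    ci_method = take(ro, "ci_method", "delong"),
    n_boot = take(ro, "n_boot", 2000L),
    seed = seed)
}

stage_dir <- function(root, name) {
  d <- file.path(root, name)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

#' Pipeline stage: simulate a cohort to disk
#' @param spec a [synthetic_spec()].
#' @param root study root directory.
#' @return the cohort directory, invisibly.
#' @export
stage_simulate <- function(spec, root) {
  write_cohort(generate_cohort(spec), root)
}

#' Pipeline stage: preprocess every subject on disk
#'
#' Reads `root/cohort`, applies the temporal preprocessing chain, writes
#' per-subject preprocessed runs, a retained-subject manifest and an
#' exclusion log to `root/preproc`.
#'
#' @param root study root directory.
#' @param config a [study_config()].
#' @return the preproc directory, invisibly.
#' @export
stage_preprocess <- function(root, config) {
  cohort <- read_cohort(root)
  pdir <- stage_dir(root, "preproc")
  rows <- list(); excl <- list()
  for (s in cohort$subjects) {
    pp <- tryCatch(
      preprocess_subject(s$bold, s$motion, cohort$masks, config$n_drop,
                         config$trans_limit_mm, config$rot_limit_deg,
                         config$band),
      error = function(e) stop("preprocess failed for subject ", s$subject_id,
                               ": ", conditionMessage(e)))
    if (pp$excluded) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group,
        max_abs_translation_mm = max(abs(pp$motion$translations_mm)),
        max_abs_rotation_deg = max(abs(pp$motion$rotations_deg)),
        stringsAsFactors = FALSE)
    } else {
      fp <- file.path(pdir, paste0(s$subject_id, "_preproc.nii.gz"))
      write_map(pp$run, fp)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, bold = basename(fp),
        stringsAsFactors = FALSE)
    }
  }
  man_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(0), group = character(0),
               bold = character(0))
  write_tsv(man_df, file.path(pdir, "manifest.tsv"))
  excl_df <- if (length(excl)) do.call(rbind, excl) else
    data.frame(subject_id = character(0), group = character(0),
               max_abs_translation_mm = numeric(0),
               max_abs_rotation_deg = numeric(0))
  write_tsv(excl_df, file.path(pdir, "exclusions.tsv"))
  write_provenance(file.path(pdir, "provenance.json"), stage = "preprocess",
                   n_drop = config$n_drop,
                   trans_limit_mm = config$trans_limit_mm,
                   rot_limit_deg = config$rot_limit_deg, band = config$band)
  invisible(pdir)
}

#' Pipeline stage: per-subject FCD maps on disk
#'
#' Reads `root/preproc`, computes raw, normalized and smoothed local and
#' long-range FCD maps per retained subject, writes them to `root/fcd`.
#'
#' @param root study root directory.
#' @param config a [study_config()].
#' @return the fcd directory, invisibly.
#' @export
stage_fcd <- function(root, config) {
  pdir <- file.path(root, "preproc")
  man <- utils::read.delim(file.path(pdir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  gray <- read_volume(file.path(root, "cohort", "mask_gray.nii.gz")) > 0.5
  fdir <- stage_dir(root, "fcd")
  rows <- list()
  for (i in seq_len(nrow(man))) {
    run <- read_bold(file.path(pdir, man$bold[i]))
    maps <- tryCatch(subject_fcd(run, gray, config$fcd),
                     error = function(e) stop("FCD failed for subject ",
                                              man$subject_id[i], ": ",
                                              conditionMessage(e)))
    kindtag <- c(local = "lfcd", long_range = "longfcd")
    for (kind in names(maps)) {
      sm <- maps[[kind]]
      base <- paste0(man$subject_id[i], "_", kindtag[kind])
      write_map(attr(sm, "raw"), file.path(fdir, paste0(base, "_raw.nii.gz")),
                geometry = run$geometry)
      write_map(attr(sm, "normalized"),
                file.path(fdir, paste0(base, "_norm.nii.gz")),
                geometry = run$geometry)
      write_map(sm, file.path(fdir, paste0(base, "_smooth.nii.gz")),
                geometry = run$geometry)
    }
    rows[[i]] <- data.frame(subject_id = man$subject_id[i],
                            group = man$group[i], stringsAsFactors = FALSE)
  }
  write_tsv(do.call(rbind, rows), file.path(fdir, "manifest.tsv"))
  write_provenance(file.path(fdir, "provenance.json"), stage = "fcd",
                   r_threshold = config$fcd$r_threshold,
                   radius_mm = config$fcd$radius_mm,
                   fwhm_mm = config$fcd$fwhm_mm)
  invisible(fdir)
}

read_smoothed_maps <- function(root, kindtag) {
  fdir <- file.path(root, "fcd")
  man <- utils::read.delim(file.path(fdir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  maps <- lapply(man$subject_id, function(id)
    read_volume(file.path(fdir, paste0(id, "_", kindtag, "_smooth.nii.gz"))))
  list(A = maps[man$group == "A"], B = maps[man$group == "B"], manifest = man)
}

#' Pipeline stage: group statistics on disk
#'
#' Reads smoothed maps from `root/fcd`, writes one-sample and two-sample
#' t-maps, the Monte-Carlo extent threshold, cluster tables and cluster
#' label volumes to `root/group`.
#'
#' @param root study root directory.
#' @param config a [study_config()].
#' @return the group directory, invisibly.
#' @export
stage_group <- function(root, config) {
  gray <- read_volume(file.path(root, "cohort", "mask_gray.nii.gz")) > 0.5
  geom <- read_bold_geometry(root)
  gdir <- stage_dir(root, "group")
  ext_log <- list()
  for (kindtag in c("lfcd", "longfcd")) {
    sm <- read_smoothed_maps(root, kindtag)
    fw <- estimate_smoothness(c(sm$A, sm$B), gray, geom,
                              groups = sm$manifest$group)
    ext <- cached_extent_threshold(gray, geom, config$correction, fw,
                                   n_a = sum(sm$manifest$group == "A"),
                                   n_b = sum(sm$manifest$group == "B"))
    ext_log[[kindtag]] <- list(extent_threshold_voxels = ext,
                               estimated_fwhm_mm = fw)
    st <- list(A = one_sample_t(sm$A, gray), B = one_sample_t(sm$B, gray),
               AB = two_sample_t(sm$A, sm$B, gray))
    write_map(st$A, file.path(gdir, paste0(kindtag, "_t_onesample_A.nii.gz")),
              geometry = geom)
    write_map(st$B, file.path(gdir, paste0(kindtag, "_t_onesample_B.nii.gz")),
              geometry = geom)
    write_map(st$AB, file.path(gdir, paste0(kindtag, "_t_twosample.nii.gz")),
              geometry = geom)
    ct <- extract_clusters(st$AB, config$correction, ext, geom)
    write_tsv(as.data.frame(ct), file.path(gdir, paste0("clusters_", kindtag, ".tsv")))
    lab <- array(0, geom$dims)
    vx <- attr(ct, "voxels")
    for (i in seq_along(vx)) lab[vx[[i]]] <- i
    write_map(lab, file.path(gdir, paste0("cluster_labels_", kindtag, ".nii.gz")),
              geometry = geom)
  }
  jsonlite::write_json(c(ext_log,
                         list(voxel_p = config$correction$voxel_p,
                              cluster_p = config$correction$cluster_p,
                              n_simulations = config$correction$n_simulations,
                              connectivity = config$correction$connectivity,
                              seed = config$correction$seed)),
                       file.path(gdir, "extent.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(file.path(gdir, "provenance.json"), stage = "group",
                   extent_thresholds = lapply(ext_log, `[[`,
                                              "extent_threshold_voxels"),
                   voxel_p = config$correction$voxel_p,
                   cluster_p = config$correction$cluster_p,
                   seed = config$correction$seed)
  invisible(gdir)
}

read_bold_geometry <- function(root) {
  img <- RNifti::readNifti(file.path(root, "cohort", "mask_gray.nii.gz"))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  hdr <- RNifti::niftiHeader(img)
  grid_geometry(dim(img)[1:3], abs(hdr$pixdim[2:4]), affine = aff)
}

#' Pipeline stage: ROC analysis of significant clusters on disk
#'
#' Reads cluster label volumes from `root/group` and smoothed maps from
#' `root/fcd`, writes per-cluster AUC tables and ROC curve points to
#' `root/roc`.
#'
#' @param root study root directory.
#' @param config a [study_config()].
#' @return the roc directory, invisibly.
#' @export
stage_roc <- function(root, config) {
  rdir <- stage_dir(root, "roc")
  for (kindtag in c("lfcd", "longfcd")) {
    sm <- read_smoothed_maps(root, kindtag)
    lab <- read_volume(file.path(root, "group",
                                 paste0("cluster_labels_", kindtag, ".nii.gz")))
    tab <- utils::read.delim(file.path(root, "group",
                                       paste0("clusters_", kindtag, ".tsv")),
                             stringsAsFactors = FALSE)
    rows <- list(); curves <- list()
    for (i in seq_len(nrow(tab))) {
      vx <- which(round(lab) == i)
      cv <- cluster_mean_values(sm$A, sm$B, vx, cluster_id = tab$cluster_id[i])
      rr <- roc_auc(cv, ci_method = config$ci_method, n_boot = config$n_boot,
                    seed = config$seed)
      rows[[i]] <- data.frame(
        kind = kindtag, cluster_id = rr$cluster_id, sign = tab$sign[i],
        size_voxels = tab$size_voxels[i], peak_t = tab$peak_t[i],
        peak_x_mm = tab$peak_x_mm[i], peak_y_mm = tab$peak_y_mm[i],
        peak_z_mm = tab$peak_z_mm[i], auc = rr$auc, ci_low = rr$ci_low,
        ci_high = rr$ci_high, p_value = rr$p_value, band = rr$band,
        positive_group = rr$positive_group, stringsAsFactors = FALSE)
      cu <- roc_curve(cv, rr$positive_group)
      cu$kind <- kindtag; cu$cluster_id <- rr$cluster_id
      curves[[i]] <- cu
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(kind = character(0), cluster_id = character(0))
    write_tsv(out, file.path(rdir, paste0("roc_", kindtag, ".tsv")))
    if (length(curves))
      utils::write.csv(do.call(rbind, curves),
                       file.path(rdir, paste0("roc_curves_", kindtag, ".csv")),
                       row.names = FALSE)
  }
  write_provenance(file.path(rdir, "provenance.json"), stage = "roc",
                   ci_method = config$ci_method, n_boot = config$n_boot,
                   seed = config$seed)
  invisible(rdir)
}

#' Run the whole pipeline on disk
#'
#' Simulate (when the config carries a [synthetic_spec()]) or reuse an
#' existing `cohort/` directory, then preprocess, map FCD, compute group
#' statistics and ROC curves. Rerunning with an identical configuration
#' reproduces all numeric outputs.
#'
#' @param config a [study_config()] (or path to a YAML file for
#'   [read_study_config()]).
#' @return the study root directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  root <- config$out
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    stage_simulate(config$simulate, root)
  } else if (!file.exists(file.path(root, "cohort", "manifest.tsv"))) {
    stop("no cohort at ", file.path(root, "cohort"),
         " and no simulation spec in the config")
  }
  stage_preprocess(root, config)
  stage_fcd(root, config)
  stage_group(root, config)
  stage_roc(root, config)
  invisible(root)
}
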