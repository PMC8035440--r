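#' Read a 4D BOLD run from a NIfTI-1 file
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param geometry optional [grid_geometry()]; when supplied, the file's
#'   grid must match and an informative error names the file otherwise.
#' @return A [bold_run()] with geometry and TR taken from the header.
#' @export
read_bold <- function(path, geometry = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D BOLD volume in '", path, "', got ", length(d), "D")
  hdr <- RNifti::niftiHeader(img)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  tr <- hdr$pixdim[5]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  geom <- grid_geometry(d[1:3], abs(hdr$pixdim[2:4]), affine = aff)
  if (!is.null(geometry) && !all(d[1:3] == geometry$dims))
    stop("grid of '", path, "' (", paste(d[1:3], collapse = "x"),
         ") does not match the configured grid (",
         paste(geometry$dims, collapse = "x"), ")")
  bold_run(array(as.numeric(img), d), geom, tr)
}

#' Write a 3D map or 4D run as NIfTI-1
#'
#' Data are stored as float32; the voxel-to-world affine is written to the
#' sform and round-trips exactly.
#'
#' @param x a [bold_run()], [fcd_map()], [stat_map()] or plain array.
#' @param path output path (.nii or .nii.gz).
#' @param geometry [grid_geometry()] (required for plain arrays).
#' @param tr_s repetition time to record for 4D data.
#' @return path, invisibly.
#' @export
write_map <- function(x, path, geometry = NULL, tr_s = NULL) {
  if (inherits(x, "bold_run")) {
    geometry <- x$geometry; tr_s <- x$tr_s; arr <- x$data
  } else if (inherits(x, "fcd_map")) {
    arr <- x$values
  } else if (inherits(x, "stat_map")) {
    arr <- x$t_values
  } else arr <- x
  stopifnot(!is.null(geometry))
  attr(arr, "pixdim") <- c(geometry$voxel_size_mm,
                           if (length(dim(arr)) == 4L && !is.null(tr_s)) tr_s)
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Read a 3D NIfTI as a plain array (used for masks and maps).
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img)[1:3])
}

#' Read a 6-column motion parameter text file
#'
#' Whitespace-delimited, one row per timepoint: translations x,y,z in mm
#' then rotations x,y,z in degrees. Extra trailing columns are ignored with
#' a note; non-numeric entries raise an error naming the line.
#'
#' @param path text file.
#' @param expected_rows optional row count (the raw run's timepoints); a
#'   mismatch is an error.
#' @return A [motion_params()].
#' @export
read_motion <- function(path, expected_rows = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) < 6L)
      stop("motion file '", path, "' line ", i, ": expected >= 6 columns, got ",
           length(parts))
    v <- suppressWarnings(as.numeric(parts[1:6]))
    if (any(is.na(v)))
      stop("motion file '", path, "' line ", i, ": non-numeric value")
    if (length(parts) > 6L && i == 1L)
      message("motion file '", path, "': ignoring ", length(parts) - 6L,
              " trailing column(s)")
    v
  })
  m <- do.call(rbind, rows)
  if (!is.null(expected_rows) && nrow(m) != expected_rows)
    stop("motion file '", path, "' has ", nrow(m), " rows but the run has ",
         expected_rows, " timepoints")
  motion_params(m)
}

write_motion <- function(motion, path) {
  m <- cbind(motion$translations_mm, motion$rotations_deg)
  utils::write.table(format(m, digits = 10, scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_provenance <- function(path, ...) {
  info <- list(..., package = "fcdensity",
               version = as.character(utils::packageVersion("fcdensity")))
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

serializable_spec <- function(spec) {
  list(dims = spec$geometry$dims, voxel_size_mm = spec$geometry$voxel_size_mm,
       n_timepoints = spec$n_timepoints, tr_s = spec$tr_s,
       n_per_group = spec$n_per_group,
       signal_band_hz = spec$signal_band_hz, ar1_coeff = spec$ar1_coeff,
       noise_sd = spec$noise_sd, motion_severity = spec$motion_severity,
       seed = spec$seed,
       n_local_hubs = lapply(spec$local_hubs, length),
       n_long_pairs = lapply(spec$long_pairs, length))
}

#' Write a synthetic cohort to disk
#'
#' Emits one 4D NIfTI and one motion .txt per subject, the four tissue
#' masks, a manifest TSV (subject_id, group, bold, motion) and a
#' provenance JSON, all under `dir/cohort/`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir study root directory (created if needed).
#' @return the cohort directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  cdir <- file.path(dir, "cohort")
  dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  geom <- cohort$spec$geometry
  for (nm in c("gray", "white", "csf", "whole_brain"))
    write_map(cohort$masks[[nm]] * 1, file.path(cdir, paste0("mask_", nm, ".nii.gz")),
              geometry = geom)
  rows <- lapply(cohort$subjects, function(s) {
    bp <- file.path(cdir, paste0(s$subject_id, "_bold.nii.gz"))
    mp <- file.path(cdir, paste0(s$subject_id, "_motion.txt"))
    write_map(s$bold, bp)
    write_motion(s$motion, mp)
    data.frame(subject_id = s$subject_id, group = s$group,
               bold = basename(bp), motion = basename(mp),
               stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, rows), file.path(cdir, "manifest.tsv"))
  write_provenance(file.path(cdir, "provenance.json"),
                   stage = "simulate", spec = serializable_spec(cohort$spec))
  invisible(cdir)
}

#' Read a cohort from a manifest directory
#'
#' @param dir study root containing `cohort/manifest.tsv`, subject files
#'   and `mask_*.nii.gz`.
#' @param tr_s repetition time override (default: from the NIfTI headers).
#' @return A cohort-shaped list (`subjects`, `masks`, `spec` holding the
#'   geometry and TR).
#' @export
read_cohort <- function(dir, tr_s = NULL) {
  cdir <- file.path(dir, "cohort")
  man <- utils::read.delim(file.path(cdir, "manifest.tsv"),
                           stringsAsFactors = FALSE)
  masks <- structure(lapply(c("gray", "white", "csf", "whole_brain"),
                            function(nm) read_volume(
                              file.path(cdir, paste0("mask_", nm, ".nii.gz"))) > 0.5),
                     names = c("gray", "white", "csf", "whole_brain"),
                     class = "tissue_masks")
  subjects <- lapply(seq_len(nrow(man)), function(i) {
    bold <- read_bold(file.path(cdir, man$bold[i]))
    if (!is.null(tr_s)) bold$tr_s <- tr_s
    motion <- read_motion(file.path(cdir, man$motion[i]),
                          expected_rows = dim(bold$data)[4])
    structure(list(bold = bold, motion = motion, group = man$group[i],
                   subject_id = man$subject_id[i]), class = "subject_data")
  })
  geom <- subjects[[1]]$bold$geometry
  spec <- list(geometry = geom, tr_s = subjects[[1]]$bold$tr_s,
               n_timepoints = dim(subjects[[1]]$bold$data)[4])
  list(subjects = subjects, masks = masks, spec = spec)
}
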