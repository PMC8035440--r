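#' A subject's 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param geometry a [grid_geometry()] matching the spatial dimensions.
#' @param tr_s repetition time in seconds.
#' @return A `bold_run` object.
#' @export
bold_run <- function(data, geometry, tr_s) {
  stopifnot(length(dim(data)) == 4L,
            all(dim(data)[1:3] == geometry$dims), tr_s > 0)
  structure(list(data = data, geometry = geometry, tr_s = tr_s),
            class = "bold_run")
}

#' Rigid-body motion parameters
#'
#' @param m t x 6 numeric matrix: translations x,y,z (mm) then rotations
#'   x,y,z (degrees), one row per timepoint.
#' @return A `motion_params` object.
#' @export
motion_params <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 6L)
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  structure(list(translations_mm = m[, 1:3, drop = FALSE],
                 rotations_deg = m[, 4:6, drop = FALSE]),
            class = "motion_params")
}

n_timepoints <- function(run) dim(run$data)[4]

# t x nvox matrix view of a 4D run (voxels in column-major spatial order).
run_matrix <- function(run) {
  d <- dim(run$data)
  t(matrix(run$data, prod(d[1:3]), d[4]))
}

matrix_to_run <- function(m, run) {
  d <- dim(run$data)
  bold_run(array(t(m), d), run$geometry, run$tr_s)
}

#' Drop initial volumes from a run and its motion trace
#'
#' Discards the first `n_drop` timepoints of both the BOLD run and the
#' aligned motion parameters (signal-equilibration volumes).
#'
#' @param run a [bold_run()].
#' @param motion a [motion_params()] with one row per run timepoint.
#' @param n_drop number of leading volumes to discard (default 10).
#' @return list(run = trimmed run, motion = trimmed motion).
#' @export
drop_initial_volumes <- function(run, motion, n_drop = 10L) {
  tt <- n_timepoints(run)
  stopifnot(nrow(motion$translations_mm) == tt)
  if (tt <= n_drop)
    stop("run has ", tt, " timepoints; cannot drop ", n_drop)
  if (n_drop == 0L) return(list(run = run, motion = motion))
  keep <- seq.int(n_drop + 1L, tt)
  list(run = bold_run(run$data[, , , keep, drop = FALSE],
                      run$geometry, run$tr_s),
       motion = motion_params(cbind(motion$translations_mm[keep, , drop = FALSE],
                                    motion$rotations_deg[keep, , drop = FALSE])))
}

#' Head-motion exclusion rule
#'
#' TRUE when the subject moved more than `trans_limit_mm` along any axis or
#' more than `rot_limit_deg` about any axis ("more than" is strict: a
#' subject at exactly the limit is retained). A TRUE return means the
#' subject must be excluded from all downstream stages.
#'
#' @param motion a [motion_params()].
#' @param trans_limit_mm translation limit in mm (default 1.5).
#' @param rot_limit_deg rotation limit in degrees (default 1.5).
#' @return logical scalar.
#' @export
motion_exceeds_limits <- function(motion, trans_limit_mm = 1.5,
                                  rot_limit_deg = 1.5) {
  tr <- motion$translations_mm
  ro <- motion$rotations_deg
  stopifnot(nrow(tr) >= 1)
  if (!all(is.finite(tr)) || !all(is.finite(ro)))
    stop("motion parameters contain non-finite values")
  max(abs(tr)) > trans_limit_mm || max(abs(ro)) > rot_limit_deg
}

#' Friston 24-parameter head-motion design
#'
#' The standard expansion of the six rigid-body parameters: the parameters
#' themselves, their one-lag copies (first row zero-padded), and the squares
#' of both sets — 24 columns.
#'
#' @param motion a [motion_params()].
#' @return A `nuisance_design`: list(columns = t x 24 matrix, column_names).
#' @export
friston24 <- function(motion) {
  m <- cbind(motion$translations_mm, motion$rotations_deg)
  tt <- nrow(m)
  lag <- rbind(0, m[-tt, , drop = FALSE])
  cols <- cbind(m, lag, m^2, lag^2)
  nm <- colnames(m)
  colnames(cols) <- c(nm, paste0(nm, "_lag"), paste0(nm, "_sq"),
                      paste0(nm, "_lag_sq"))
  structure(list(columns = cols, column_names = colnames(cols)),
            class = "nuisance_design")
}

#' Full nuisance design: Friston-24 plus tissue signals and derivatives
#'
#' Appends to the Friston-24 design the whole-brain (global), white-matter
#' and CSF mean time series and their first-difference temporal derivatives
#' (first row zero-padded): 30 columns.
#'
#' @param run a [bold_run()].
#' @param masks a `tissue_masks` object on the run's grid.
#' @param motion a [motion_params()] aligned with the run.
#' @return A `nuisance_design` with 30 columns.
#' @export
build_nuisance <- function(run, masks, motion) {
  fr <- friston24(motion)
  m <- run_matrix(run)
  tiss <- list(global = masks$whole_brain, wm = masks$white, csf = masks$csf)
  cols <- fr$columns
  for (nm in names(tiss)) {
    idx <- which(tiss[[nm]])
    if (!length(idx)) stop("tissue mask '", nm, "' is empty")
    s <- rowMeans(m[, idx, drop = FALSE])
    ds <- c(0, diff(s))
    cols <- cbind(cols, s, ds)
    colnames(cols)[ncol(cols) - 1:0] <- c(nm, paste0(nm, "_deriv"))
  }
  structure(list(columns = cols, column_names = colnames(cols)),
            class = "nuisance_design")
}

#' Regress nuisance covariates out of every voxel series
#'
#' Ordinary least squares of each voxel time series on the design plus an
#' intercept; the run is replaced by the residuals, which are orthogonal to
#' every design column. Rank-deficient designs are handled by dropping
#' linearly dependent columns with a warning.
#'
#' @param run a [bold_run()].
#' @param design a `nuisance_design` with rows matching run timepoints.
#' @return The residual [bold_run()].
#' @export
nuisance_regress <- function(run, design) {
  tt <- n_timepoints(run)
  stopifnot(nrow(design$columns) == tt)
  m <- run_matrix(run)
  res <- regress_out(m, design$columns)
  matrix_to_run(res, run)
}

# OLS residuals of every column of m on [intercept | X], dropping linearly
# dependent columns of X with a warning.
regress_out <- function(m, X) {
  X <- cbind(intercept = 1, X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    warning("dropping ", length(drop),
            " linearly dependent nuisance column(s): ",
            paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  qr.resid(qx, m)
}

# Linear detrend + zero-phase frequency-domain bandpass of a t x n matrix.
bandpass_matrix <- function(m, tr_s, low_hz, high_hz) {
  tt <- nrow(m)
  m <- qr.resid(qr(cbind(1, seq_len(tt))), m)
  g <- band_gain(tt, tr_s, low_hz, high_hz, taper = TRUE)
  Re(stats::mvfft(stats::mvfft(m) * g, inverse = TRUE)) / tt
}

# The detrend+bandpass chain is linear in time, so it is one t x t
# operator: Q = Re(F^H diag(gain) F) / t composed with the detrending
# projection. Cached per (t, TR, band) so a cohort pays the FFTs once.
.bp_cache <- new.env(parent = emptyenv())

bandpass_operator <- function(tt, tr_s, low_hz, high_hz) {
  key <- paste(tt, signif(tr_s, 10), low_hz, high_hz, sep = "|")
  op <- .bp_cache[[key]]
  if (is.null(op)) {
    g <- band_gain(tt, tr_s, low_hz, high_hz, taper = TRUE)
    fb <- Re(stats::mvfft(stats::mvfft(diag(tt)) * g, inverse = TRUE)) / tt
    X <- cbind(1, seq_len(tt))
    pd <- diag(tt) - X %*% solve(crossprod(X), t(X))
    op <- fb %*% pd
    .bp_cache[[key]] <- op
  }
  op
}

#' Linear detrend and 0.01-0.1 Hz bandpass filter
#'
#' Removes each voxel's linear trend, then applies a zero-phase
#' frequency-domain band window with a raised-cosine taper one frequency
#' bin wide at each edge. Pure tones inside the band retain essentially all
#' their amplitude; tones well outside, and linear drifts, are suppressed.
#'
#' @param run a [bold_run()].
#' @param low_hz,high_hz band edges in Hz (defaults 0.01 and 0.1).
#' @return The filtered [bold_run()].
#' @export
detrend_bandpass <- function(run, low_hz = 0.01, high_hz = 0.1) {
  tt <- n_timepoints(run)
  nyq <- 1 / (2 * run$tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band [", low_hz, ", ", high_hz,
         "] Hz must lie strictly inside (0, Nyquist = ", nyq, " Hz)")
  matrix_to_run(bandpass_matrix(run_matrix(run), run$tr_s, low_hz, high_hz),
                run)
}

#' Run the full temporal preprocessing chain on one subject
#'
#' Fixed stage order: drop initial volumes, motion-based exclusion check,
#' nuisance regression (Friston-24 + global/WM/CSF + derivatives), linear
#' detrend + bandpass. Excluded subjects are returned with `excluded =
#' TRUE` and no processed run.
#'
#' @param bold a [bold_run()].
#' @param motion a [motion_params()] aligned with the raw run.
#' @param masks a `tissue_masks` object.
#' @param n_drop initial volumes to discard (default 10).
#' @param trans_limit_mm,rot_limit_deg exclusion limits (defaults 1.5/1.5).
#' @param band bandpass edges in Hz (default c(0.01, 0.1)).
#' @return list(run, motion, excluded).
#' @export
preprocess_subject <- function(bold, motion, masks, n_drop = 10L,
                               trans_limit_mm = 1.5, rot_limit_deg = 1.5,
                               band = c(0.01, 0.1)) {
  dr <- drop_initial_volumes(bold, motion, n_drop)
  if (motion_exceeds_limits(dr$motion, trans_limit_mm, rot_limit_deg))
    return(list(run = NULL, motion = dr$motion, excluded = TRUE))
  run <- dr$run
  tt <- n_timepoints(run)
  nyq <- 1 / (2 * run$tr_s)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq))
    stop("band [", band[1], ", ", band[2],
         "] Hz must lie strictly inside (0, Nyquist = ", nyq, " Hz)")
  # regression and filtering are restricted to in-brain voxels; outside-brain
  # voxels are zeroed (the tissue masks are subsets of whole_brain, so the
  # nuisance design is unchanged)
  d <- run$geometry$dims
  brain <- which(masks$whole_brain)
  mb <- t(matrix(run$data, prod(d), tt)[brain, , drop = FALSE])
  fr <- friston24(dr$motion)$columns
  tiss <- NULL
  for (nm in c("whole_brain", "white", "csf")) {
    sub <- match(which(masks[[nm]]), brain)
    if (anyNA(sub) || !length(sub)) stop("tissue mask '", nm,
                                         "' is empty or not inside whole_brain")
    s <- rowMeans(mb[, sub, drop = FALSE])
    tiss <- cbind(tiss, s, c(0, diff(s)))
  }
  mb <- regress_out(mb, cbind(fr, tiss))
  mb <- bandpass_operator(tt, run$tr_s, band[1], band[2]) %*% mb
  if (!all(is.finite(mb)))
    stop("preprocessing produced non-finite values")
  full <- matrix(0, prod(d), tt)
  full[brain, ] <- t(mb)
  list(run = bold_run(array(full, c(d, tt)), run$geometry, run$tr_s),
       motion = dr$motion, excluded = FALSE)
}
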