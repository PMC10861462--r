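#' Drop initial volumes
#'
#' Removes the first \code{n_drop} frames of a scan (and the matching
#' motion rows), the standard guard against magnetization (T1
#' saturation) effects at scan start.
#'
#' @param scan a \code{subject_scan}.
#' @param n_drop number of leading frames to remove (default 10).
#' @return The truncated \code{subject_scan}.
#' @export
drop_initial_volumes <- function(scan, n_drop = 10L) {
  Tn <- ncol(scan$signal)
  if (n_drop >= Tn) stop("n_drop must be smaller than the number of frames")
  if (n_drop == 0) return(scan)
  keep <- (n_drop + 1):Tn
  scan$signal <- scan$signal[, keep, drop = FALSE]
  scan$motion <- scan$motion[keep, , drop = FALSE]
  if (!is.null(scan$true_latent))
    scan$true_latent <- scan$true_latent[keep, , drop = FALSE]
  scan
}

#' Framewise displacement (Power convention)
#'
#' FD at frame t is the sum of absolute backward differences of the six
#' rigid-body parameters, with the three rotations (radians) converted
#' to arc length on a sphere of \code{radius_mm}. The first frame has
#' FD = 0 by convention.
#'
#' @param motion T x 6 matrix: 3 translations (mm), 3 rotations (rad).
#' @param radius_mm head-sphere radius for the rotation arc (default 50).
#' @return List of class \code{motion_trace}: \code{fd} (length T) and
#'   \code{mean_fd}.
#' @export
compute_fd <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (!all(is.finite(motion))) stop("non-finite motion values")
  Tn <- nrow(motion)
  fd <- numeric(Tn)
  if (Tn > 1) {
    d <- abs(diff(motion))
    fd[-1] <- rowSums(d[, 1:3, drop = FALSE]) +
      radius_mm * rowSums(d[, 4:6, drop = FALSE])
  }
  structure(list(fd = fd, mean_fd = mean(fd)), class = "motion_trace")
}

#' Friston-24 motion regressor expansion
#'
#' Expands six rigid-body parameters R into the 24-column set
#' \code{[R, R^2, R_lag1, R_lag1^2]}; lagged columns are zero-padded at
#' the first frame.
#'
#' @param motion T x 6 matrix.
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion) {
  R <- as.matrix(motion)
  stopifnot(ncol(R) == 6)
  Rl <- rbind(0, R[-nrow(R), , drop = FALSE])
  cbind(R, R^2, Rl, Rl^2)
}

#' Nuisance regression
#'
#' Replaces each voxel series by its least-squares residual against an
#' intercept, an optional linear trend, and the supplied nuisance
#' regressors (e.g. Friston-24 motion, global mean, white matter, CSF).
#' Collinear design columns are dropped with a warning.
#'
#' @param scan a \code{subject_scan}.
#' @param regressors T x p nuisance matrix (may be NULL).
#' @param include_trend add a linear trend column (detrending).
#' @return The scan with residualized \code{signal}.
#' @export
regress_nuisance <- function(scan, regressors = NULL, include_trend = TRUE) {
  Tn <- ncol(scan$signal)
  X <- cbind(intercept = rep(1, Tn))
  if (include_trend) X <- cbind(X, trend = seq_len(Tn) - (Tn + 1) / 2)
  if (!is.null(regressors)) {
    regressors <- as.matrix(regressors)
    if (nrow(regressors) != Tn) stop("regressor rows must match frames")
    X <- cbind(X, regressors)
  }
  if (ncol(X) >= Tn) stop("more design columns than frames")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient nuisance design: dropped ",
            ncol(X) - qrX$rank, " collinear column(s)")
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    qrX <- qr(X)
  }
  Y <- t(scan$signal)                         # T x V
  scan$signal <- t(qr.resid(qrX, Y))
  scan
}

#' Zero-phase band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to each
#' voxel series; the canonical resting-state band is 0.01-0.1 Hz.
#'
#' @param scan a \code{subject_scan} (uses \code{scan$tr}).
#' @param low_hz,high_hz band edges in Hz.
#' @param order Butterworth design order (per pass).
#' @return The filtered scan.
#' @export
bandpass <- function(scan, low_hz = 0.01, high_hz = 0.1, order = 4) {
  fs <- 1 / scan$tr
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  # demean first: the band excludes DC, and removing it up front avoids
  # the filter's start-up transient on the mean level
  scan$signal <- t(apply(scan$signal - rowMeans(scan$signal), 1, function(x)
    signal::filtfilt(bf, x)))
  scan
}

#' Motion scrubbing by cubic-spline interpolation
#'
#' Frames whose framewise displacement exceeds \code{fd_thresh} are
#' replaced, per voxel, by cubic-spline interpolation over the clean
#' frames. Flagged frames before the first (after the last) clean frame
#' take the nearest clean value, since splines do not extrapolate
#' stably.
#'
#' @param scan a \code{subject_scan}.
#' @param trace a \code{\link{compute_fd}} result aligned with the scan.
#' @param fd_thresh FD threshold in mm (default 0.5).
#' @return The scrubbed scan.
#' @export
scrub_interpolate <- function(scan, trace, fd_thresh = 0.5) {
  fd <- trace$fd
  Tn <- ncol(scan$signal)
  stopifnot(length(fd) == Tn)
  bad <- which(fd > fd_thresh)
  if (length(bad) == 0) return(scan)
  clean <- setdiff(seq_len(Tn), bad)
  if (length(clean) < 4) stop("fewer than 4 clean frames: cannot scrub")
  lo <- min(clean); hi <- max(clean)
  interior <- bad[bad > lo & bad < hi]
  Y <- scan$signal
  if (length(interior) > 0) {
    Y[, interior] <- t(apply(Y, 1, function(x)
      spline(clean, x[clean], xout = interior, method = "natural")$y))
  }
  if (any(bad < lo)) Y[, bad[bad < lo]] <- Y[, lo]
  if (any(bad > hi)) Y[, bad[bad > hi]] <- Y[, hi]
  scan$signal <- Y
  scan
}

#' Exclude high-motion subjects
#'
#' Removes subjects whose mean framewise displacement exceeds
#' \code{max_mean_fd} or whose maximum absolute translation exceeds
#' \code{max_abs_motion_voxels} voxel widths.
#'
#' @param scans list of \code{subject_scan}.
#' @param max_mean_fd mean-FD ceiling in mm (default 0.5).
#' @param max_abs_motion_voxels translation ceiling in voxel widths.
#' @param voxel_size_mm voxel width in mm (default 3).
#' @return List with \code{scans} (survivors) and \code{report}
#'   (data.frame of excluded subject_id + reason).
#' @export
exclude_subjects <- function(scans, max_mean_fd = 0.5,
                             max_abs_motion_voxels = 1, voxel_size_mm = 3) {
  reasons <- character(0); ids <- character(0)
  keep <- logical(length(scans))
  lim <- max_abs_motion_voxels * voxel_size_mm
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    mfd <- compute_fd(s$motion)$mean_fd
    maxt <- max(abs(s$motion[, 1:3]))
    why <- character(0)
    if (mfd > max_mean_fd) why <- c(why, sprintf("mean FD %.3f > %.3f", mfd, max_mean_fd))
    if (maxt > lim) why <- c(why, sprintf("max translation %.2f mm > %.2f mm", maxt, lim))
    if (length(why) > 0) {
      ids <- c(ids, s$subject_id)
      reasons <- c(reasons, paste(why, collapse = "; "))
    } else keep[i] <- TRUE
  }
  if (!any(keep)) stop("all subjects excluded")
  list(scans = scans[keep],
       report = data.frame(subject_id = ids, reason = reasons,
                           stringsAsFactors = FALSE))
}

#' Standard preprocessing chain for one scan
#'
#' Runs the numerical stages in their canonical order: volume dropping,
#' detrending + nuisance regression (Friston-24 expansion of the motion
#' trace), band-pass filtering, then FD-based scrubbing.
#'
#' @param scan a \code{subject_scan}.
#' @param n_drop leading frames to drop.
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param fd_thresh scrubbing threshold (mm).
#' @param extra_regressors optional additional T x p nuisance columns
#'   (aligned with the scan after dropping).
#' @return The preprocessed \code{subject_scan}; its \code{mean_fd}
#'   field records the post-drop mean FD.
#' @export
preprocess_scan <- function(scan, n_drop = 10L, low_hz = 0.01, high_hz = 0.1,
                            fd_thresh = 0.5, extra_regressors = NULL) {
  scan <- drop_initial_volumes(scan, n_drop)
  reg <- friston24(scan$motion)
  if (!is.null(extra_regressors)) reg <- cbind(reg, extra_regressors)
  scan <- regress_nuisance(scan, reg, include_trend = TRUE)
  scan <- bandpass(scan, low_hz, high_hz)
  trace <- compute_fd(scan$motion)
  scan <- scrub_interpolate(scan, trace, fd_thresh)
  scan$mean_fd <- trace$mean_fd
  scan
}
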