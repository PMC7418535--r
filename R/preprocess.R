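# Timeseries cleaning and quality control: framewise displacement and
# spike scrubbing, per-run standardization, temporal bandpass, 24-parameter
# motion regression, COV-based voxel exclusion, and participant-level QC.

#' Framewise displacement from a six-parameter motion trace
#'
#' FD at scan i is the sum of absolute successive differences of the six
#' rigid-body parameters (translations in mm; rotations pre-converted to mm
#' equivalents, conventionally on a 50 mm sphere). The first scan of each
#' run is 0 by convention.
#'
#' @param motion scans x 6 numeric matrix.
#' @param run optional integer run label per scan; FD resets at run starts.
#' @param threshold spike threshold in mm (default 0.5).
#' @return an object of class `fd_series` with elements `fd`, `threshold`,
#'   `run`.
#' @export
framewise_displacement <- function(motion, run = NULL, threshold = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop("motion trace must have exactly 6 columns (3 translations, 3 rotations)")
  if (nrow(motion) < 1) stop("motion trace must contain at least one scan")
  if (any(!is.finite(motion))) stop("motion parameters must be finite")
  if (is.null(run)) run <- rep(1L, nrow(motion))
  fd <- numeric(nrow(motion))
  for (idx in split(seq_len(nrow(motion)), run)) {
    if (length(idx) > 1)
      fd[idx[-1]] <- rowSums(abs(diff(motion[idx, , drop = FALSE])))
    fd[idx[1]] <- 0
  }
  structure(list(fd = fd, threshold = threshold, run = as.integer(run)),
            class = "fd_series")
}

#' @export
print.fd_series <- function(x, ...) {
  cat(sprintf("Framewise displacement: %d scans, %d over %.2f mm (max %.3f mm)\n",
              length(x$fd), sum(x$fd > x$threshold), x$threshold, max(x$fd)))
  invisible(x)
}

#' Scrub motion spikes from a timeseries
#'
#' Marks as removed exactly the scans whose framewise displacement exceeds
#' the threshold. Scans are dropped (not interpolated) by downstream
#' correlation.
#'
#' @param ts a [roi_timeseries].
#' @param fd an `fd_series` aligned to the scans of `ts`.
#' @return `ts` with an updated `scan_mask`.
#' @export
scrub_spikes <- function(ts, fd) {
  stopifnot(inherits(ts, "roi_timeseries"), inherits(fd, "fd_series"))
  if (length(fd$fd) != nrow(ts$values))
    stop("framewise displacement series does not align with the timeseries")
  ts$scan_mask <- ts$scan_mask & (fd$fd <= fd$threshold)
  if (!any(ts$scan_mask))
    warning("all scans exceeded the motion threshold; no scans retained")
  ts
}

#' Temporal bandpass filter (zero-phase Butterworth)
#'
#' Applies a forward-backward (zero-phase) Butterworth bandpass of the given
#' order to each ROI within each run. The default 0.01-0.08 Hz band retains
#' the low-frequency fluctuations that carry resting-state connectivity and
#' suppresses drift (below band) and respiratory/cardiac aliasing (above).
#'
#' @param ts a [roi_timeseries] with known repetition time.
#' @param low,high band edges in Hz.
#' @param order Butterworth order per band edge (default 4).
#' @return the filtered [roi_timeseries].
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08, order = 4L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr)
  if (high >= nyq)
    stop(sprintf("upper band edge (%g Hz) must be below Nyquist (%g Hz)",
                 high, nyq))
  if (low <= 0 || low >= high) stop("band edges must satisfy 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  warmup <- 3 * (length(bf$b) + length(bf$a))
  for (idx in run_indices(ts)) {
    if (length(idx) <= warmup)
      stop(sprintf("run of %d scans is too short for the filter warm-up (%d)",
                   length(idx), warmup))
    # demean before filtering: DC lies below the passband anyway, and
    # removing it first suppresses forward-backward edge transients
    ts$values[idx, ] <- apply(ts$values[idx, , drop = FALSE], 2,
                              function(col) signal::filtfilt(bf, col - mean(col)))
  }
  ts
}

# Friston-style 24-regressor design: 6 current parameters, 6 previous-scan
# parameters (zero-padded at each run start), and the squares of those 12.
motion24_design <- function(motion, run) {
  motion <- as.matrix(motion)
  prev <- motion * 0
  for (idx in split(seq_len(nrow(motion)), run))
    if (length(idx) > 1)
      prev[idx[-1], ] <- motion[idx[-length(idx)], , drop = FALSE]
  X <- cbind(motion, prev, motion^2, prev^2)
  colnames(X) <- c(paste0("m", 1:6), paste0("m", 1:6, "_lag"),
                   paste0("m", 1:6, "_sq"), paste0("m", 1:6, "_lag_sq"))
  X
}

#' Regress 24 motion nuisance parameters out of a timeseries
#'
#' Least-squares residualization against 24 regressors (six rigid-body
#' parameters, the same six from the previous scan, and the squares of
#' those twelve) plus an intercept. Residuals are numerically orthogonal to
#' the regressor span; a rank-deficient design is handled by the
#' pivoting QR (equivalent to a pseudoinverse fit) with a warning.
#'
#' @param ts a [roi_timeseries].
#' @param motion scans x 6 motion matrix aligned to `ts`.
#' @return the residual [roi_timeseries] (mean-removed).
#' @export
regress_motion24 <- function(ts, motion) {
  stopifnot(inherits(ts, "roi_timeseries"))
  motion <- as.matrix(motion)
  if (nrow(motion) != nrow(ts$values) || ncol(motion) != 6)
    stop("motion must be a scans x 6 matrix aligned to the timeseries")
  X <- cbind(intercept = 1, motion24_design(motion, ts$run))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    warning(sprintf("nuisance design is rank deficient (rank %d of %d); %s",
                    qrX$rank, ncol(X),
                    "fit uses the pivoted QR pseudoinverse"))
  ts$values <- qr.resid(qrX, ts$values)
  ts
}

#' Per-run mean centering and variance normalization, then concatenation
#'
#' Each ROI's series is z-scored within each run (mean 0, SD 1) before runs
#' are concatenated, so runs contribute equally to the pooled correlation.
#'
#' @param ts a [roi_timeseries] (possibly multi-run).
#' @return the standardized [roi_timeseries].
#' @export
center_whiten_concatenate <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  for (idx in run_indices(ts)) {
    block <- ts$values[idx, , drop = FALSE]
    sds <- apply(block, 2, stats::sd)
    if (any(sds == 0))
      stop("zero-variance series in ROI(s): ",
           paste(ts$roi_names[sds == 0], collapse = ", "))
    ts$values[idx, ] <- scale(block)
  }
  ts
}

#' COV-based voxel exclusion within a Gaussian spatial neighborhood
#'
#' For each voxel, the coefficient-of-variation (COV) mean and SD are
#' computed over the ROI's voxels with Gaussian distance weights
#' (sigma = 5 mm by default, the voxel itself included). A voxel is
#' excluded iff its COV exceeds the neighborhood mean by more than
#' `cutoff` neighborhood SDs; ties (e.g. a uniform ROI, where the local SD
#' is 0) are kept.
#'
#' @param coords voxels x 3 matrix of coordinates in mm.
#' @param cov per-voxel COV (non-negative).
#' @param sigma Gaussian neighborhood width in mm (default 5).
#' @param cutoff exclusion threshold in neighborhood SDs (default 0.5).
#' @return logical vector, `TRUE` = keep.
#' @export
cov_voxel_mask <- function(coords, cov, sigma = 5, cutoff = 0.5) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("need at least two voxels")
  if (length(cov) != nrow(coords)) stop("cov must align with coords")
  if (any(cov < 0) || any(!is.finite(coords))) stop("invalid COV or coordinates")
  d2 <- as.matrix(stats::dist(coords))^2
  W <- exp(-d2 / (2 * sigma^2))
  mu <- as.numeric(W %*% cov) / rowSums(W)
  v <- as.numeric(W %*% (cov^2)) / rowSums(W) - mu^2
  sd_n <- sqrt(pmax(v, 0))
  keep <- !(cov > mu + cutoff * sd_n)
  if (!any(keep)) warning("all voxels excluded by the COV rule")
  keep
}

#' Participant-level quality control
#'
#' Excludes participants with (1) any ROI below `min_voxels` voxels,
#' (2) any anatomic ROI with more than `max_missing` of its voxels missing
#' from the functional scans, or (3) any ROI whose temporal SNR falls more
#' than `snr_sd` SDs below the sample mean for that ROI. ROIs listed in
#' `exempt_rois` (by default the olfactory tubercle, a very small structure)
#' are exempt from all three criteria.
#'
#' @param stats_df data frame with columns `participant`, `roi`,
#'   `n_voxels`, `frac_present`, `snr`.
#' @param min_voxels minimum voxel count (default 50).
#' @param max_missing maximum missing-voxel fraction (default 0.6).
#' @param snr_sd SNR exclusion depth in SDs (default 3).
#' @param exempt_rois ROIs exempt from all criteria (default `"OTB"`).
#' @return a data frame, one row per participant: `participant`,
#'   `included`, `reasons` (comma-separated reason codes, `""` if included).
#' @export
qc_participants <- function(stats_df, min_voxels = 50, max_missing = 0.6,
                            snr_sd = 3, exempt_rois = "OTB") {
  need <- c("participant", "roi", "n_voxels", "frac_present", "snr")
  if (!all(need %in% names(stats_df)))
    stop("stats_df must contain columns: ", paste(need, collapse = ", "))
  if (length(unique(stats_df$participant)) < 2)
    stop("participant QC needs at least two participants (SNR criterion)")
  if (any(is.na(stats_df[need])))
    stop("missing ROI statistics in stats_df")
  df <- stats_df[!(stats_df$roi %in% exempt_rois), , drop = FALSE]
  # per-ROI SNR reference distribution across the full sample
  snr_mean <- tapply(df$snr, df$roi, mean)
  snr_sdev <- tapply(df$snr, df$roi, stats::sd)
  lo <- snr_mean[df$roi] - snr_sd * snr_sdev[df$roi]
  df$fail_voxels <- df$n_voxels < min_voxels
  df$fail_missing <- (1 - df$frac_present) > max_missing
  df$fail_snr <- df$snr < lo
  out <- do.call(rbind, lapply(split(df, df$participant), function(d) {
    reasons <- c(if (any(d$fail_voxels)) "min_voxels",
                 if (any(d$fail_missing)) "missing_voxels",
                 if (any(d$fail_snr)) "low_snr")
    data.frame(participant = d$participant[1],
               included = length(reasons) == 0,
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Run the full cleaning chain on a raw timeseries
#'
#' Applies, in order: per-run mean centering and variance normalization,
#' per-run temporal bandpass, 24-parameter motion regression, and framewise
#' displacement scrubbing. The order of bandpass and motion regression can
#' be swapped via `bandpass_first = FALSE`.
#'
#' @param ts a raw [roi_timeseries].
#' @param motion scans x 6 motion matrix aligned to `ts`.
#' @param fd_threshold scrubbing threshold in mm.
#' @param low,high bandpass edges in Hz.
#' @param bandpass_first if `FALSE`, regress motion before filtering.
#' @return the cleaned [roi_timeseries] with scrubbed scans masked.
#' @export
preprocess_timeseries <- function(ts, motion, fd_threshold = 0.5,
                                  low = 0.01, high = 0.08,
                                  bandpass_first = TRUE) {
  ts <- center_whiten_concatenate(ts)
  if (bandpass_first) {
    ts <- bandpass(ts, low, high)
    ts <- regress_motion24(ts, motion)
  } else {
    ts <- regress_motion24(ts, motion)
    ts <- bandpass(ts, low, high)
  }
  fd <- framewise_displacement(motion, run = ts$run, threshold = fd_threshold)
  scrub_spikes(ts, fd)
}
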