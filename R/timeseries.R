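#' ROI timeseries container
#'
#' Holds multi-run, ROI-averaged BOLD timeseries together with the metadata
#' the cleaning chain needs: run labels, the repetition time, and a per-scan
#' retention mask updated by motion scrubbing.
#'
#' @param values numeric matrix, scans x ROIs; column names are ROI labels.
#' @param tr repetition time in seconds (> 0).
#' @param run integer run label per scan (rows of `values`).
#' @param roi_names optional ROI labels; defaults to `colnames(values)`.
#' @param scan_mask logical per-scan retention flag; defaults to all `TRUE`.
#' @return an object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr, run = rep(1L, nrow(values)),
                           roi_names = colnames(values),
                           scan_mask = rep(TRUE, nrow(values))) {
  values <- as.matrix(values)
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(values)))
  if (anyDuplicated(roi_names)) stop("roi_names must be unique")
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0)
    stop("repetition_time (tr) must be a positive scalar")
  if (length(run) != nrow(values)) stop("run labels must align with scans")
  if (length(scan_mask) != nrow(values)) stop("scan_mask must align with scans")
  if (any(!is.finite(values[scan_mask, , drop = FALSE])))
    stop("retained scans contain non-finite values")
  colnames(values) <- roi_names
  structure(list(values = values, roi_names = roi_names,
                 run = as.integer(run), tr = tr,
                 scan_mask = as.logical(scan_mask)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("ROI timeseries: %d scans x %d ROIs, %d run(s), TR = %g s\n",
              nrow(x$values), ncol(x$values), length(unique(x$run)), x$tr))
  n_out <- sum(!x$scan_mask)
  if (n_out > 0) cat(sprintf("  %d scan(s) flagged for removal\n", n_out))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

# retained-scan values
retained_values <- function(ts) ts$values[ts$scan_mask, , drop = FALSE]

# split scan indices by run, in run order of first appearance
run_indices <- function(ts) split(seq_along(ts$run), ts$run)
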