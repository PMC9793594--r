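#' Connectivity matrix construction and transforms
#'
#' A connectivity matrix is a symmetric ROI x ROI matrix of Pearson
#' correlations between regional time series, carried around as a plain
#' numeric matrix with a `variant` attribute (`"raw"`, `"nonneg"` or
#' `"fisher_z"`) and ROI ids in its dimnames.
#'
#' @name connectivity
NULL

new_connectivity_matrix <- function(values, roi_order, variant) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(roi_order)) roi_order <- paste0("roi", seq_len(nrow(values)))
  dimnames(values) <- list(roi_order, roi_order)
  attr(values, "variant") <- variant
  class(values) <- c("connectivity_matrix", class(values))
  values
}

fc_variant <- function(x) attr(x, "variant") %||% "raw"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compute a subject's functional connectivity matrix
#'
#' Builds the ROI x ROI Pearson correlation matrix from a time x ROI
#' time-series table. The diagonal is exactly 1.
#'
#' @param ts numeric matrix or data frame, rows = time points, columns = ROIs.
#'   Column names (if present) become the ROI order.
#' @return A `"raw"`-variant connectivity matrix.
#' @export
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 3L) stop("need at least 3 time points, got ", nrow(ts))
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% which(sds == 0)
    stop("constant time series for ROI(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  r <- stats::cor(ts)
  diag(r) <- 1
  new_connectivity_matrix(r, colnames(ts), "raw")
}

#' Zero out negative correlations
#'
#' Replaces every negative entry with 0, the convention used before profile
#' deviation is computed (the physiological meaning of negative resting-state
#' correlations being ambiguous). Idempotent; symmetry is preserved. The raw
#' matrix can be kept instead for the sensitivity re-run.
#'
#' @param c a `"raw"` (or already `"nonneg"`) connectivity matrix.
#' @return A `"nonneg"`-variant connectivity matrix.
#' @export
zero_negatives <- function(c) {
  if (!fc_variant(c) %in% c("raw", "nonneg"))
    stop("zero_negatives expects a raw connectivity matrix")
  v <- pmax(unclass(c), 0)
  new_connectivity_matrix(v, rownames(c), "nonneg")
}

#' Fisher z-transform a correlation matrix
#'
#' Applies arctanh to every off-diagonal entry; the diagonal is set to 0 and
#' excluded from all downstream statistics. Group comparisons run on this
#' variant of the raw (negatives retained) matrix.
#'
#' @param c a `"raw"`-variant connectivity matrix with off-diagonal |r| < 1.
#' @return A `"fisher_z"`-variant matrix.
#' @export
fisher_z <- function(c) {
  if (fc_variant(c) != "raw")
    stop("fisher_z expects a raw connectivity matrix")
  v <- unclass(c)
  off <- abs(v) >= 1
  diag(off) <- FALSE
  if (any(off))
    stop("off-diagonal |r| >= 1; degenerate subject (perfectly correlated ROIs)")
  z <- atanh(v)
  diag(z) <- 0
  new_connectivity_matrix(z, rownames(c), "fisher_z")
}

#' Flag high-motion frames
#'
#' Marks every frame whose framewise displacement exceeds `fd_threshold`,
#' together with the `window` preceding and following frames (clipped at the
#' run boundaries), and reports the flagged fraction.
#'
#' @param fd numeric vector of per-frame framewise displacement (mm).
#' @param fd_threshold displacement above which a frame is a motion spike (mm).
#' @param window frames flagged on each side of a spike.
#' @return list with `mask` (logical, TRUE = flagged) and `fraction`.
#' @export
flag_high_motion <- function(fd, fd_threshold = 0.5, window = 2L) {
  if (length(fd) == 0L) stop("empty motion trace")
  if (any(fd < 0)) stop("framewise displacement must be nonnegative")
  if (fd_threshold <= 0) stop("fd_threshold must be positive")
  n <- length(fd)
  mask <- logical(n)
  for (i in which(fd > fd_threshold)) {
    lo <- max(1L, i - window)
    hi <- min(n, i + window)
    mask[lo:hi] <- TRUE
  }
  list(mask = mask, fraction = sum(mask) / n)
}

#' Motion-based subject exclusion rule
#'
#' A subject is excluded when *more than* `max_fraction` of frames are
#' flagged as high motion (strict inequality: exactly 50% is kept).
#'
#' @param fraction flagged fraction from [flag_high_motion()].
#' @param max_fraction exclusion bound (default 0.5).
#' @return TRUE if the subject should be excluded.
#' @export
qc_exclude <- function(fraction, max_fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  fraction > max_fraction
}
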