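#' Framewise displacement
#'
#' Power-style scalar head-motion summary: sum of absolute frame-to-frame
#' differences of the three translations plus `head_radius` times the sum of
#' absolute rotation differences (small-angle arc length on a sphere of the
#' given radius). The first frame is 0 by convention.
#'
#' @param motion Frames x 6 matrix: translations (mm) then rotations (rad).
#' @param head_radius Sphere radius in mm (default 50).
#' @return Numeric vector of per-frame FWD in mm.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2 || ncol(motion) != 6)
    stop("motion must be a frames x 6 matrix with >= 2 frames")
  d <- abs(diff(motion))
  fwd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fwd)
}

#' Friston-24 motion expansion
#'
#' Volterra expansion of the six rigid-body parameters: the parameters, their
#' squares, their one-frame lags, and the squared lags (24 columns). The lag
#' of the first frame is zero-padded.
#'
#' @param motion Frames x 6 matrix.
#' @return Frames x 24 matrix with labeled columns.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2 || ncol(motion) != 6)
    stop("motion must be a frames x 6 matrix with >= 2 frames")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, motion^2, lag1, lag1^2)
  base <- c("tx", "ty", "tz", "rx", "ry", "rz")
  colnames(out) <- c(base, paste0(base, "_sq"),
                     paste0(base, "_lag"), paste0(base, "_lag_sq"))
  out
}

#' Spike regressors for high-motion frames
#'
#' One binary indicator column per frame whose framewise displacement
#' strictly exceeds the threshold (default 500 microns = 0.5 mm).
#'
#' @param fwd Per-frame FWD in mm.
#' @param threshold_mm Threshold in mm (default 0.5).
#' @return Frames x n_spikes 0/1 matrix (zero columns if no frame flagged).
#' @export
spike_regressors <- function(fwd, threshold_mm = 0.5) {
  flagged <- which(fwd > threshold_mm)
  out <- matrix(0, length(fwd), length(flagged))
  if (length(flagged))
    out[cbind(flagged, seq_along(flagged))] <- 1
  colnames(out) <- if (length(flagged)) paste0("spike_", flagged) else character(0)
  out
}

#' Assemble a nuisance design matrix
#'
#' Binds Friston-24 motion columns, optional externally supplied
#' physiological components, and spike indicators. Continuous columns are
#' linearly detrended to match the detrended BOLD data; binary spike columns
#' are left as indicators. All-zero columns are dropped.
#'
#' @param motion Frames x 6 motion matrix, or NULL.
#' @param physio Optional frames x k matrix of physiological components.
#' @param spikes Optional frames x s spike matrix from [spike_regressors()].
#' @return Frames x p design matrix (possibly zero columns).
#' @export
nuisance_design <- function(motion = NULL, physio = NULL, spikes = NULL) {
  parts <- list()
  if (!is.null(motion)) parts$motion <- .detrend_cols(friston24(motion))
  if (!is.null(physio)) parts$physio <- .detrend_cols(as.matrix(physio))
  if (!is.null(spikes) && ncol(spikes) > 0) parts$spikes <- spikes
  if (!length(parts)) stop("no regressors supplied")
  X <- do.call(cbind, unname(parts))
  keep <- colSums(abs(X)) > 0
  X[, keep, drop = FALSE]
}

.detrend_cols <- function(X) {
  t_idx <- seq_len(nrow(X))
  stats::resid(stats::lm.fit(cbind(1, t_idx), X))
}

#' Scale, detrend and residualize regional timeseries
#'
#' Global signal scaling (the session-wide median over all nodes and frames
#' is mapped to 1,000), per-node linear detrending, then ordinary
#' least-squares residualization against the nuisance design (an intercept
#' and linear trend are always included in the projection). Rank-deficient
#' designs are handled by pivoting; redundant columns are dropped with a
#' warning. Residuals are orthogonal to every retained design column.
#'
#' @param ts Nodes x frames matrix.
#' @param design Frames x p design matrix, or NULL/zero-column for none.
#' @param scale_median Target median (default 1000); set NULL to skip
#'   scaling.
#' @return Nodes x frames residual matrix (attributes of `ts` preserved).
#' @export
clean_timeseries <- function(ts, design = NULL, scale_median = 1000) {
  ts <- as.matrix(ts)
  nf <- ncol(ts)
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (ncol(design) > 0 && nrow(design) != nf)
      stop("design frames do not match timeseries frames")
  }
  if (!is.null(scale_median)) {
    med <- stats::median(ts)
    if (med <= 0) stop("non-positive global median; cannot scale")
    ts <- ts * (scale_median / med)
  }
  t_idx <- seq_len(nf)
  X <- cbind(intercept = 1, trend = t_idx)
  if (!is.null(design) && ncol(design) > 0) X <- cbind(X, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    warning("dropping rank-deficient design columns: ",
            paste(dropped, collapse = ", "))
  }
  res <- t(qr.resid(qx, t(ts)))
  # restore the scaled baseline so the output stays on the BOLD-like scale
  # (keeps a second pass through this function a near-no-op)
  if (!is.null(scale_median)) res <- res + scale_median
  attributes(res)[c("tr_seconds", "session_id")] <-
    attributes(ts)[c("tr_seconds", "session_id")]
  res
}
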