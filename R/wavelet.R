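#' First eigenvariate of a voxels-by-time matrix
#'
#' Summary timecourse of a region: the first right singular vector of the
#' voxel x time matrix, scaled by the first singular value over the square
#' root of the voxel count (singular-value-weighted amplitude), with its
#' sign fixed so that the correlation with the voxel-mean timecourse is
#' non-negative.
#'
#' @param voxels_by_time Voxels x frames matrix.
#' @return Numeric timecourse of length `ncol(voxels_by_time)`.
#' @export
first_eigenvariate <- function(voxels_by_time) {
  X <- as.matrix(voxels_by_time)
  if (nrow(X) < 1 || ncol(X) < 2)
    stop("need at least 1 voxel and 2 frames")
  if (all(X == 0)) {
    warning("all-zero input; returning zero timecourse")
    return(numeric(ncol(X)))
  }
  sv <- svd(X, nu = 0, nv = 1)
  tc <- sv$v[, 1] * sv$d[1] / sqrt(nrow(X))
  m <- colMeans(X)
  s <- sum(tc * (m - mean(m)))
  if (s == 0) s <- sum(tc * m)
  if (s < 0) tc <- -tc
  tc
}

# Least-asymmetric Daubechies filter of length 8 (scaling coefficients).
.la8_g <- c(-0.07576571478934, -0.02963552764600, 0.49761866763246,
            0.80373875180522, 0.29785779560554, -0.09921954357695,
            -0.01260396726226, 0.03222310060407)

.modwt_filters <- function() {
  g <- .la8_g
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)     # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# circularly shift x right by k (k >= 0)
.circ_lag <- function(x, k) {
  n <- length(x)
  k <- k %% n
  if (k == 0) return(x)
  c(x[(n - k + 1):n], x[1:(n - k)])
}

#' Maximal overlap discrete wavelet transform (LA8)
#'
#' Non-decimated pyramid transform with periodic boundary handling. Returns
#' wavelet (detail) coefficients `W1..WJ` and the level-J scaling
#' coefficients `VJ`; [imodwt()] inverts it exactly.
#'
#' @param x Numeric series.
#' @param n_levels Number of decomposition levels J.
#' @return List with `W` (list of J coefficient vectors), `V` (level-J
#'   scaling coefficients), `n_levels`.
#' @export
modwt <- function(x, n_levels = 6L) {
  flt <- .modwt_filters()
  n <- length(x)
  if (n < (2^(n_levels - 1)) * (flt$L - 1) + 1)
    stop("series too short for ", n_levels, " MODWT levels")
  W <- vector("list", n_levels)
  V <- x
  for (j in seq_len(n_levels)) {
    step <- 2^(j - 1)
    Wj <- numeric(n); Vj <- numeric(n)
    for (l in seq_len(flt$L)) {
      shifted <- .circ_lag(V, (l - 1) * step)
      Wj <- Wj + flt$h[l] * shifted
      Vj <- Vj + flt$g[l] * shifted
    }
    W[[j]] <- Wj
    V <- Vj
  }
  list(W = W, V = V, n_levels = n_levels)
}

#' Inverse MODWT
#'
#' @param w A decomposition from [modwt()].
#' @return The reconstructed series.
#' @export
imodwt <- function(w) {
  flt <- .modwt_filters()
  V <- w$V
  n <- length(V)
  for (j in rev(seq_len(w$n_levels))) {
    step <- 2^(j - 1)
    Vnew <- numeric(n)
    for (l in seq_len(flt$L)) {
      Vnew <- Vnew + flt$h[l] * .circ_lag(w$W[[j]], -(l - 1) * step) +
        flt$g[l] * .circ_lag(V, -(l - 1) * step)
    }
    V <- Vnew
  }
  V
}

#' Nominal MODWT passband
#'
#' Detail level j covers `[fs / 2^(j+1), fs / 2^j]` Hz; a set of levels
#' spans from the deepest level's lower edge to the shallowest level's
#' upper edge.
#'
#' @param tr_seconds Sampling interval in seconds.
#' @param levels Integer detail levels (default 3:6).
#' @return Named numeric vector `c(lower, upper)` in Hz.
#' @export
modwt_band_limits <- function(tr_seconds, levels = 3:6) {
  fs <- 1 / tr_seconds
  c(lower = fs / 2^(max(levels) + 1), upper = fs / 2^min(levels))
}

#' Band-limit a timecourse to selected MODWT detail levels
#'
#' Decomposes the series with the shift-invariant LA8 MODWT (reflection
#' boundary: the series is concatenated with its mirror image before the
#' periodic transform, and the first half of the reconstruction is kept) and
#' reconstructs from the selected detail levels only. With levels 3-6 at
#' TR 0.72 s the nominal passband is approximately 0.011-0.174 Hz.
#'
#' @param x Numeric series.
#' @param levels Detail levels to retain (default 3:6).
#' @return Band-limited series, same length as `x`.
#' @export
modwt_bandlimit <- function(x, levels = 3:6) {
  J <- max(levels)
  flt <- .modwt_filters()
  if (2 * length(x) < (2^(J - 1)) * (flt$L - 1) + 1)
    stop("series too short for MODWT level ", J)
  xr <- c(x, rev(x))                       # reflection boundary
  w <- modwt(xr, n_levels = J)
  for (j in seq_len(J)) if (!(j %in% levels)) w$W[[j]][] <- 0
  w$V[] <- 0
  y <- imodwt(w)
  y[seq_along(x)]
}

#' Band-limit every node of a regional timeseries matrix
#'
#' @param ts Nodes x frames matrix.
#' @param levels Detail levels to retain.
#' @return Matrix of the same shape (attributes preserved).
#' @export
modwt_bandlimit_matrix <- function(ts, levels = 3:6) {
  out <- t(apply(ts, 1, modwt_bandlimit, levels = levels))
  attributes(out)[c("tr_seconds", "session_id")] <-
    attributes(ts)[c("tr_seconds", "session_id")]
  out
}
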