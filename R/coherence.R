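# Windowed segment FFTs for all nodes.
# Returns complex array (nodes x bins x segments), bin frequencies, and L.
.welch_fft <- function(X, tr, window = 128L, overlap = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X); nf <- ncol(X)
  if (window > nf) stop("Welch window longer than the series")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- seq(1L, nf - window + 1L, by = step)
  L <- length(starts)
  if (L < 4L) stop("need at least 4 Welch segments; shorten the window")
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(window - 1)) / window)   # Hann
  nb <- window %/% 2L
  Z <- array(complex(real = 0), dim = c(n, nb, L))
  for (s in seq_len(L)) {
    seg <- X[, starts[s]:(starts[s] + window - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, `*`)
    F <- t(stats::mvfft(t(seg)))
    Z[, , s] <- F[, 2:(nb + 1L), drop = FALSE]     # drop DC
  }
  freqs <- (1:nb) / (window * tr)
  list(Z = Z, freqs = freqs, L = L, window = window, overlap = overlap)
}

# per-bin magnitude-squared coherence matrices from a .welch_fft() result
.msc_by_bin <- function(wf, bins) {
  n <- dim(wf$Z)[1]
  acc <- matrix(0, n, n)
  for (b in bins) {
    Zb <- wf$Z[, b, , drop = TRUE]
    if (is.null(dim(Zb))) Zb <- matrix(Zb, nrow = n)   # single segment guard
    S <- Zb %*% Conj(t(Zb))
    pw <- Re(diag(S))
    if (any(pw <= 0)) stop("zero-variance node in Welch segment spectra")
    acc <- acc + Mod(S)^2 / outer(pw, pw)
  }
  acc / length(bins)
}

.band_bins <- function(freqs, band) {
  eps <- 1e-9
  which(freqs >= band[1] - eps & freqs <= band[2] + eps)
}

#' Band-averaged magnitude-squared coherence between two timecourses
#'
#' Welch cross-spectral estimate `|Sxy(f)|^2 / (Sxx(f) Syy(f))` averaged
#' over the frequency bins inside `band`, clipped to `[0, 1]` against
#' rounding. Hann window, mean removed per segment.
#'
#' @param x,y Equal-length numeric series.
#' @param tr_seconds Sampling interval (s).
#' @param band Frequency interval in Hz (default the wavelet 3-6 band).
#' @param window Segment length in frames (default 128).
#' @param overlap Fractional overlap (default 0.5).
#' @return Scalar coherence in `[0, 1]`, with attribute `L` (number of
#'   Welch segments).
#' @export
ms_coherence <- function(x, y, tr_seconds,
                         band = modwt_band_limits(tr_seconds),
                         window = 128L, overlap = 0.5) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input; coherence undefined")
  wf <- .welch_fft(rbind(x, y), tr_seconds, window, overlap)
  bins <- .band_bins(wf$freqs, band)
  if (!length(bins)) stop("no frequency bins inside the requested band")
  C <- .msc_by_bin(wf, bins)
  out <- min(max(C[1, 2], 0), 1)
  attr(out, "L") <- wf$L
  out
}

#' Magnitude-squared coherence matrix for one session
#'
#' Band-limits every node's series to the selected MODWT detail levels,
#' then estimates band-averaged Welch magnitude-squared coherence for all
#' node pairs. The diagonal is set to 1 by definition and excluded from all
#' edge statistics downstream.
#'
#' @param ts Nodes x frames matrix with a `tr_seconds` attribute (or pass
#'   `tr_seconds`).
#' @param tr_seconds Sampling interval; defaults to the matrix attribute.
#' @param levels MODWT detail levels retained before coherence (default
#'   3:6); NULL to skip band-limiting.
#' @param band Frequency band averaged over (default: nominal band of
#'   `levels`).
#' @param window,overlap Welch parameters (defaults 128 frames, 50%).
#' @return Symmetric n x n matrix of class `coherence_matrix` with
#'   attributes `L`, `welch_window`, `band`, `thresholded`, `session_id`.
#' @export
coherence_matrix <- function(ts, tr_seconds = attr(ts, "tr_seconds"),
                             levels = 3:6,
                             band = NULL,
                             window = 128L, overlap = 0.5) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 2) stop("need at least 2 nodes")
  if (is.null(tr_seconds)) stop("tr_seconds not supplied")
  if (is.null(band))
    band <- if (is.null(levels)) c(0, Inf) else modwt_band_limits(tr_seconds, levels)
  if (any(apply(ts, 1, stats::sd) == 0))
    stop("zero-variance node; coherence undefined")
  if (!is.null(levels)) ts <- modwt_bandlimit_matrix(ts, levels)
  wf <- .welch_fft(ts, tr_seconds, window, overlap)
  bins <- .band_bins(wf$freqs, band)
  if (!length(bins)) stop("no frequency bins inside the requested band")
  C <- .msc_by_bin(wf, bins)
  C <- pmin(pmax(C, 0), 1)
  C <- (C + t(C)) / 2
  diag(C) <- 1
  structure(C, class = c("coherence_matrix", "matrix"),
            L = wf$L, welch_window = wf$window, band = band,
            thresholded = FALSE, session_id = attr(ts, "session_id"))
}

#' FDR-threshold a coherence matrix
#'
#' Per-edge p-values from the classical independence null of the Welch
#' magnitude-squared coherence estimator, `P(C > c) = (1 - c)^(L - 1)`
#' (the estimate is Beta(1, L-1) under zero true coherence), are corrected
#' across all unique edges with Benjamini-Hochberg; sub-threshold entries
#' are set to 0. The diagonal is untouched.
#'
#' @param m A [coherence_matrix()].
#' @param n_segments L; defaults to the matrix's `L` attribute.
#' @param q FDR level (default 0.05).
#' @return Thresholded matrix (attribute `thresholded = TRUE`).
#' @export
fdr_threshold_matrix <- function(m, n_segments = attr(m, "L"), q = 0.05) {
  if (is.null(n_segments) || n_segments < 2)
    stop("n_segments (L) must be >= 2")
  v <- vectorize_edges(m)
  p <- (1 - v)^(n_segments - 1)
  keep <- stats::p.adjust(p, method = "BH") <= q
  v[!keep] <- 0
  out <- devectorize_edges(v, nrow(m))
  diag(out) <- 1
  attributes(out)[c("L", "welch_window", "band", "session_id")] <-
    attributes(m)[c("L", "welch_window", "band", "session_id")]
  attr(out, "thresholded") <- TRUE
  class(out) <- c("coherence_matrix", "matrix")
  out
}
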