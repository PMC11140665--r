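#' Edge index map for an n-node graph
#'
#' Unordered node pairs in row-major upper-triangle order with 0-based ids:
#' (0,1), (0,2), ..., (0,n-1), (1,2), ...
#'
#' @param n_nodes Number of nodes.
#' @return Data.frame with columns `i`, `j` and `n * (n - 1) / 2` rows.
#' @export
edge_index <- function(n_nodes) {
  idx <- which(lower.tri(diag(n_nodes)), arr.ind = TRUE)
  data.frame(i = idx[, "col"] - 1L, j = idx[, "row"] - 1L)
}

#' Vectorize the unique edges of a symmetric matrix
#'
#' @param m Symmetric matrix.
#' @param tol Symmetry tolerance (default 1e-8 relative).
#' @return Numeric vector in [edge_index()] order.
#' @export
vectorize_edges <- function(m, tol = 1e-8) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m) ||
      max(abs(m - t(m))) > tol * max(1, max(abs(m))))
    stop("matrix is not symmetric")
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_edges()]; the diagonal is set to 0.
#'
#' @param v Edge vector of length `n * (n - 1) / 2`.
#' @param n_nodes Number of nodes.
#' @return Symmetric n x n matrix with zero diagonal.
#' @export
devectorize_edges <- function(v, n_nodes) {
  if (length(v) != n_nodes * (n_nodes - 1) / 2)
    stop("edge vector length does not match n_nodes")
  m <- matrix(0, n_nodes, n_nodes)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Stack per-session coherence matrices into an edges-by-sessions matrix
#'
#' @param matrices List of symmetric coherence matrices (same size).
#' @return Edges x sessions matrix; rows follow [edge_index()] order.
#' @export
edge_vector_set <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  E <- sapply(matrices, vectorize_edges)
  attr(E, "n_nodes") <- nrow(matrices[[1]])
  E
}

.zscore_rows <- function(E) {
  mu <- rowMeans(E)
  sdv <- apply(E, 1, stats::sd)
  list(z = (E - mu) / sdv, sd = sdv)
}

# residualizer matrix for covariates (always includes an intercept)
.resid_maker <- function(n, covariates = NULL) {
  C <- cbind(rep(1, n), covariates)
  qc <- qr(C)
  diag(n) - tcrossprod(qr.Q(qc)[, seq_len(qc$rank), drop = FALSE])
}

#' Edgewise standardized regression of coherence on a hormone
#'
#' For every edge, coherence across sessions and the hormone series are
#' z-scored and the standardized slope is estimated by ordinary least
#' squares. Without covariates the slope equals the Pearson correlation;
#' with covariates the hormone's partial standardized coefficient and the
#' partial-correlation t statistic are returned. Zero-variance edges get NA
#' statistics and are excluded from inference.
#'
#' @param edges Edges x sessions matrix (see [edge_vector_set()]).
#' @param hormone Hormone concentration per session (any units; slopes are
#'   invariant to affine rescaling).
#' @param covariates Optional sessions x k matrix (e.g. time-since-waking).
#' @return An `edgewise_map`: list with `beta_z`, `t`, `r_partial`, `df`,
#'   `n_sessions`, `n_nodes`, `covariate_names`.
#' @export
edgewise_regression <- function(edges, hormone, covariates = NULL) {
  edges <- as.matrix(edges)
  n <- ncol(edges)
  if (length(hormone) != n) stop("hormone length must equal session count")
  if (n < 4) stop("need at least 4 sessions")
  if (stats::sd(hormone) == 0) stop("hormone series has zero variance")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  M <- .resid_maker(n, if (k) as.matrix(covariates) else NULL)
  hz <- as.numeric(scale(hormone))
  hr <- as.numeric(M %*% hz)
  ze <- .zscore_rows(edges)
  bad <- ze$sd == 0
  Ez <- ze$z
  Ez[bad, ] <- 0
  Er <- Ez %*% M
  num <- as.numeric(unname(Er %*% hr))
  enorm <- unname(sqrt(rowSums(Er^2)))
  hnorm <- sqrt(sum(hr^2))
  r <- num / (enorm * hnorm)
  beta <- num / hnorm^2                        # slope in z units
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - pmin(r^2, 1 - 1e-15)))
  r[bad] <- NA_real_; beta[bad] <- NA_real_; tstat[bad] <- NA_real_
  if (any(bad))
    message(sum(bad), " zero-variance edges excluded from inference")
  structure(list(beta_z = beta, t = tstat, r_partial = r, df = df,
                 n_sessions = n, n_nodes = attr(edges, "n_nodes"),
                 covariate_names = colnames(covariates)),
            class = "edgewise_map")
}

# all permutations of 1..n (n small)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, factorial(n), n)
  row <- 1L
  for (k in seq_len(n)) {
    block <- cbind(k, ifelse(sub >= k, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Permutation null for the edgewise regression
#'
#' One session-relabeling per iteration, applied identically to all edges
#' (equivalent to permuting the hormone vector), preserving the dependence
#' between edges. Two-tailed p per edge is the proportion of permuted
#' statistics whose absolute value equals or exceeds the observed one
#' (ties count as exceedances), floored at 1/B. If `B` is at least the
#' number of distinct permutations, the test switches to exhaustive
#' enumeration with a warning.
#'
#' @param edges Edges x sessions matrix.
#' @param hormone Hormone per session.
#' @param covariates Optional sessions x k covariate matrix (permutations
#'   keep covariates fixed and permute the hormone).
#' @param B Number of permutations (default 10000, minimum 100).
#' @param seed Integer seed for the permutation schedule.
#' @return The [edgewise_regression()] map augmented with `p`, `B`,
#'   `exhaustive`, `seed`.
#' @export
permutation_null <- function(edges, hormone, covariates = NULL,
                             B = 10000L, seed = 1L) {
  if (B < 100) stop("B must be at least 100")
  map <- edgewise_regression(edges, hormone, covariates)
  n <- map$n_sessions
  exhaustive <- FALSE
  n_distinct <- if (n <= 12) factorial(n) else Inf
  if (n_distinct <= B) {
    warning("B >= ", n_distinct, " distinct permutations; ",
            "switching to exhaustive enumeration")
    perms <- t(.all_perms(n))
    exhaustive <- TRUE
  } else {
    set.seed(seed)
    perms <- replicate(B, sample.int(n))
  }
  Bn <- ncol(perms)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  M <- .resid_maker(n, if (k) as.matrix(covariates) else NULL)
  hz <- as.numeric(scale(hormone))
  H <- M %*% matrix(hz[perms], n, Bn)
  hnorm <- sqrt(colSums(H^2))
  ze <- .zscore_rows(edges)
  ok <- which(ze$sd > 0)
  Ez <- ze$z[ok, , drop = FALSE] %*% M
  enorm <- sqrt(rowSums(Ez^2))
  # |t| comparisons are equivalent to |partial r| comparisons at fixed df
  R_perm <- abs((Ez %*% H) / (enorm %o% hnorm))
  r_obs <- abs(map$r_partial[ok])
  count <- rowSums(R_perm >= r_obs - 1e-12)
  p <- rep(NA_real_, length(map$t))
  p[ok] <- pmax(count / Bn, 1 / Bn)
  map$p <- p
  map$B <- Bn
  map$exhaustive <- exhaustive
  map$seed <- seed
  map
}

#' Dual thresholding of an edgewise map
#'
#' Display mask: permutation p below `p_alpha` (default 0.001). Strength
#' mask: Benjamini-Hochberg adjusted q at or below `q` (default 0.05) across
#' all edges with finite statistics; used downstream for nodal association
#' strengths. Signed t statistics are retained on masked edges.
#'
#' @param map Output of [permutation_null()].
#' @param p_alpha Display threshold on permutation p.
#' @param q FDR level for the strength mask.
#' @return The map augmented with `q_value`, `display_mask`,
#'   `strength_mask` (logical vectors over edges).
#' @export
threshold_map <- function(map, p_alpha = 0.001, q = 0.05) {
  if (is.null(map$p)) stop("map carries no permutation p-values")
  qv <- rep(NA_real_, length(map$p))
  ok <- !is.na(map$p)
  qv[ok] <- stats::p.adjust(map$p[ok], method = "BH")
  map$q_value <- qv
  map$display_mask <- ok & map$p < p_alpha
  map$strength_mask <- ok & qv <= q
  map$p_alpha <- p_alpha
  map$q <- q
  map
}

#' Spearman similarity between two edgewise maps
#'
#' Rank correlation of the unthresholded edge statistics of two maps over
#' the common (finite) edge set, with `df = n_edges - 2` and a t-based
#' two-tailed p-value.
#'
#' @param a,b Edgewise maps over the same edge set.
#' @param stat Which statistic to compare (default `"t"`).
#' @return List with `rho`, `df`, `p`, `n_edges`.
#' @export
compare_maps <- function(a, b, stat = "t") {
  x <- a[[stat]]; y <- b[[stat]]
  if (length(x) != length(y)) stop("maps cover different edge sets")
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) stop("too few comparable edges")
  rho <- stats::cor(x[ok], y[ok], method = "spearman")
  df <- n - 2L
  tt <- rho * sqrt(df / max(1 - rho^2, 1e-15))
  list(rho = rho, df = df, p = 2 * stats::pt(-abs(tt), df), n_edges = n)
}
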