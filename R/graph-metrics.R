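#' Within-network weighted global efficiency
#'
#' For each network, the efficiency of the induced weighted subgraph:
#' edge lengths are the reciprocal coherence weights, shortest paths are
#' computed on those lengths, and efficiency is the mean of inverse path
#' lengths over ordered node pairs (disconnected pairs contribute 0). The
#' session value is the mean across networks with at least two nodes.
#'
#' @param m Coherence matrix (typically FDR-thresholded), weights in [0,1].
#' @param parcellation Parcellation lookup.
#' @param mode `"within"` (default): average of per-network efficiencies;
#'   `"whole"`: efficiency of the full graph.
#' @param length_fun Mapping from weight to length (default `1/w`).
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(m, parcellation,
                              mode = c("within", "whole"),
                              length_fun = function(w) 1 / w) {
  mode <- match.arg(mode)
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == nrow(parcellation))
  eff_one <- function(sub) {
    n <- nrow(sub)
    if (n < 2) return(NA_real_)
    diag(sub) <- 0
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if (igraph::ecount(g) == 0) return(0)
    d <- igraph::distances(g, weights = length_fun(igraph::E(g)$weight))
    inv <- 1 / d
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n * (n - 1))
  }
  if (mode == "whole") return(eff_one(m))
  effs <- vapply(unique(parcellation$network), function(nw) {
    idx <- which(parcellation$network == nw)
    if (length(idx) < 2) {
      warning("network ", nw, " has fewer than 2 nodes; skipped")
      return(NA_real_)
    }
    eff_one(m[idx, idx, drop = FALSE])
  }, numeric(1))
  mean(effs, na.rm = TRUE)
}

#' Mean weighted participation coefficient
#'
#' Per node, `P = 1 - sum_s (k_is / k_i)^2` where `k_is` is the node's total
#' coherence weight into network s and `k_i` its total strength; the session
#' value is the mean over nodes with nonzero strength. Measures how evenly a
#' node's weight is spread across the nine networks.
#'
#' @param m Coherence matrix (typically FDR-thresholded).
#' @param parcellation Parcellation lookup.
#' @return Scalar in [0, 1].
#' @export
participation_coefficient <- function(m, parcellation) {
  m <- unclass(as.matrix(m))
  stopifnot(nrow(m) == nrow(parcellation))
  diag(m) <- 0
  k <- rowSums(m)
  if (all(k == 0)) {
    warning("all nodes isolated; participation undefined")
    return(NA_real_)
  }
  ks <- t(rowsum(t(m), parcellation$network))    # nodes x networks
  p <- pmax(1 - rowSums((ks / k)^2), 0)          # guard -eps at single-module nodes
  mean(p[k > 0])
}

#' Session-level graph metrics table
#'
#' @param matrices List of (thresholded) coherence matrices, one per session.
#' @param parcellation Parcellation lookup.
#' @param session_table Session table with `session_id` and `time_label`.
#' @return Data.frame: `session_id`, `time_label`, `efficiency`,
#'   `participation`.
#' @export
session_graph_metrics <- function(matrices, parcellation, session_table) {
  stopifnot(length(matrices) == nrow(session_table))
  data.frame(
    session_id = session_table$session_id,
    time_label = session_table$time_label,
    efficiency = vapply(matrices, global_efficiency, numeric(1),
                        parcellation = parcellation),
    participation = vapply(matrices, participation_coefficient, numeric(1),
                           parcellation = parcellation),
    stringsAsFactors = FALSE
  )
}

#' Welch comparison of a session metric between morning and evening
#'
#' Welch two-sample t test (AM minus PM) with Welch-Satterthwaite degrees
#' of freedom, plus Cohen's d computed with the pooled SD.
#'
#' @param metrics Table from [session_graph_metrics()] (or any data.frame
#'   with `time_label` and the metric column).
#' @param field Metric column name.
#' @return List with `t`, `df_welch`, `p`, `cohens_d`, `mean_am`, `mean_pm`.
#' @export
am_pm_compare <- function(metrics, field) {
  x <- metrics[[field]][metrics$time_label == "AM"]
  y <- metrics[[field]][metrics$time_label == "PM"]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 sessions per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both groups; test undefined")
  tt <- stats::t.test(x, y)
  sp <- sqrt(((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  list(t = unname(tt$statistic), df_welch = unname(tt$parameter),
       p = tt$p.value, cohens_d = (mean(x) - mean(y)) / sp,
       mean_am = mean(x), mean_pm = mean(y))
}
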