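#' Signed nodal association strengths
#'
#' Treats the FDR-masked edgewise t statistics as a signed weighted graph
#' and sums, per node, the suprathreshold positive edge statistics
#' (positive strength) and the absolute values of the suprathreshold
#' negative ones (negative strength), computed independently.
#'
#' @param map A thresholded edgewise map (see [threshold_map()]).
#' @param parcellation Parcellation lookup (`node_id`, `network`).
#' @param mask Which mask to apply: `"strength"` (default) or `"display"`.
#' @return Data.frame: `node_id`, `network`, `positive_strength`,
#'   `negative_strength`.
#' @export
nodal_strengths <- function(map, parcellation, mask = c("strength", "display")) {
  mask <- match.arg(mask)
  msk <- if (mask == "strength") map$strength_mask else map$display_mask
  if (is.null(msk)) stop("map has not been thresholded; run threshold_map()")
  n <- map$n_nodes
  if (is.null(n)) n <- (1 + sqrt(1 + 8 * length(map$t))) / 2
  if (nrow(parcellation) != n)
    stop("parcellation size does not match the map's node count")
  tv <- ifelse(msk & !is.na(map$t), map$t, 0)
  m <- devectorize_edges(tv, n)
  data.frame(
    node_id = parcellation$node_id,
    network = parcellation$network,
    positive_strength = rowSums(pmax(m, 0)),
    negative_strength = rowSums(pmax(-m, 0)),
    stringsAsFactors = FALSE
  )
}

#' Per-network mean strengths with 95% confidence intervals
#'
#' Node-level strengths are averaged within each network; the interval is
#' the t-based 95% CI across nodes. Singleton networks are flagged with NA
#' intervals.
#'
#' @param strengths Output of [nodal_strengths()].
#' @return Data.frame: `network`, `direction`, `n_nodes`, `mean`,
#'   `ci95_lo`, `ci95_hi`.
#' @export
network_summary <- function(strengths) {
  if (nrow(strengths) == 0) stop("empty strength table")
  out <- do.call(rbind, lapply(split(strengths, strengths$network), function(d) {
    summ <- function(x, dir) {
      n <- length(x); m <- mean(x)
      if (n < 2) {
        warning("singleton network; CI undefined")
        half <- NA_real_
      } else {
        half <- stats::qt(0.975, n - 1) * stats::sd(x) / sqrt(n)
      }
      data.frame(network = d$network[1], direction = dir, n_nodes = n,
                 mean = m, ci95_lo = m - half, ci95_hi = m + half,
                 stringsAsFactors = FALSE)
    }
    rbind(summ(d$positive_strength, "positive"),
          summ(d$negative_strength, "negative"))
  }))
  rownames(out) <- NULL
  out
}

.strength_long <- function(tables, factor_name, direction) {
  col <- paste0(direction, "_strength")
  do.call(rbind, lapply(names(tables), function(nm) {
    d <- tables[[nm]]
    data.frame(strength = d[[col]], group = nm, network = d$network,
               node_id = d$node_id, stringsAsFactors = FALSE)
  }))
}

# shared two-way fixed-effects ANOVA: strength ~ A * network,
# Type II sums of squares for main effects, Tukey HSD on both margins
.two_way_strength_anova <- function(long, factor_name) {
  long$group <- factor(long$group)
  long$network <- factor(long$network)
  tab <- table(long$group, long$network)
  if (any(tab == 0)) stop("empty ", factor_name, " x network cell")
  fit <- stats::lm(strength ~ group * network, data = long)
  a2 <- car::Anova(fit, type = 2)
  rn <- rownames(a2)
  rn[rn == "group"] <- factor_name
  rn[rn == "group:network"] <- paste0(factor_name, ":network")
  anova_table <- data.frame(
    term = rn,
    sum_sq = a2[["Sum Sq"]],
    df = a2[["Df"]],
    f = a2[["F value"]],
    p = a2[["Pr(>F)"]],
    stringsAsFactors = FALSE
  )
  aovfit <- stats::aov(strength ~ group + network, data = long)
  tukey <- suppressWarnings(stats::TukeyHSD(aovfit, which = c("group", "network")))
  names(tukey)[names(tukey) == "group"] <- factor_name
  list(anova = anova_table, tukey = tukey,
       residual_df = a2["Residuals", "Df"], fit = fit)
}

#' Hormone-by-network ANOVA on nodal strengths
#'
#' Two-way fixed-effects ANOVA with interaction on node-level strengths
#' pooled across hormones (each node contributes one observation per
#' hormone), followed by Tukey HSD on the hormone and network margins.
#' With 415 nodes and 3 hormones the residual df is 3*415 - 27 = 1218.
#'
#' @param strength_tables Named list (one [nodal_strengths()] table per
#'   hormone) over identical node sets.
#' @param direction `"positive"` or `"negative"` strengths.
#' @return List with `anova` (term, sum_sq, df, f, p), `tukey`,
#'   `residual_df`.
#' @export
hormone_network_anova <- function(strength_tables,
                                  direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(is.list(strength_tables), length(strength_tables) >= 2,
            !is.null(names(strength_tables)))
  ids <- lapply(strength_tables, `[[`, "node_id")
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]])))
    stop("strength tables must cover identical node sets")
  long <- .strength_long(strength_tables, "hormone", direction)
  .two_way_strength_anova(long, "hormone")
}

#' Sex-by-network ANOVA on nodal strengths
#'
#' Same model as [hormone_network_anova()] with participant (sex) as the
#' second factor; with 415 nodes per participant the residual df is
#' 2*415 - 18 = 812.
#'
#' @param strength_tables Named list of two [nodal_strengths()] tables
#'   (one per participant), over the same parcellation.
#' @param direction `"positive"` or `"negative"`.
#' @return As [hormone_network_anova()].
#' @export
sex_network_anova <- function(strength_tables,
                              direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(length(strength_tables) == 2, !is.null(names(strength_tables)))
  long <- .strength_long(strength_tables, "sex", direction)
  .two_way_strength_anova(long, "sex")
}

#' Strongest nodes by association strength
#'
#' @param strengths A [nodal_strengths()] table.
#' @param k Number of nodes to return.
#' @param direction `"positive"` or `"negative"`.
#' @return The top-k rows, sorted descending with ties broken by lower
#'   `node_id`.
#' @export
top_nodes <- function(strengths, k = 10L,
                      direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  col <- paste0(direction, "_strength")
  ord <- order(-strengths[[col]], strengths$node_id)
  out <- strengths[ord[seq_len(min(k, nrow(strengths)))], , drop = FALSE]
  if (all(strengths[[col]] == 0))
    attr(out, "degenerate") <- TRUE
  rownames(out) <- NULL
  out
}
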