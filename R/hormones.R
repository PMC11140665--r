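#' Diurnal summary for one analyte
#'
#' Morning and evening means/SDs and the percent morning-to-evening
#' decrease, `100 * (mean_am - mean_pm) / mean_am`. Missing rows (e.g.
#' serum-free sessions) are skipped. Full precision is returned; round at
#' the reporting layer if integer percentages are wanted.
#'
#' @param table Session table with `time_label` and analyte columns.
#' @param analyte Column name of the analyte.
#' @return List with `mean_am`, `sd_am`, `mean_pm`, `sd_pm`, `pct_decrease`,
#'   `n_am`, `n_pm`.
#' @export
summarize_diurnal <- function(table, analyte) {
  if (!analyte %in% names(table)) stop("unknown analyte: ", analyte)
  x <- table[[analyte]]
  am <- x[table$time_label == "AM"]; am <- am[!is.na(am)]
  pm <- x[table$time_label == "PM"]; pm <- pm[!is.na(pm)]
  if (length(am) < 2 || length(pm) < 2)
    stop("need at least 2 AM and 2 PM observations for ", analyte)
  m_am <- mean(am); m_pm <- mean(pm)
  if (m_am == 0) stop("AM mean is zero; percent decrease undefined")
  list(mean_am = m_am, sd_am = stats::sd(am),
       mean_pm = m_pm, sd_pm = stats::sd(pm),
       pct_decrease = 100 * (m_am - m_pm) / m_am,
       n_am = length(am), n_pm = length(pm))
}

#' Pairwise correlation screen with Bonferroni correction
#'
#' Pearson correlations between every `x_vars` x `y_vars` pair, optionally within AM-only or PM-only sessions, with two-tailed
#' p-values and a Bonferroni-corrected significance flag. Missing values are
#' handled pairwise (serum rows are absent on some sessions); no imputation.
#'
#' @param table Session table.
#' @param x_vars,y_vars Column names to correlate.
#' @param subset `"all"`, `"AM"` or `"PM"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_family Bonferroni divisor; defaults to the number of
#'   correlations actually computed in this screen.
#' @return Tidy data.frame: `var_x`, `var_y`, `subset`, `n`, `r`, `p`,
#'   `significant`. Zero-variance pairs get `NA` statistics and a FALSE flag.
#' @export
correlation_screen <- function(table, x_vars, y_vars, subset = "all",
                               alpha = 0.05, n_family = NULL) {
  subset <- match.arg(subset, c("all", "AM", "PM"))
  if (subset != "all") table <- table[table$time_label == subset, , drop = FALSE]
  pairs <- expand.grid(var_x = x_vars, var_y = y_vars,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    x <- table[[pairs$var_x[k]]]; y <- table[[pairs$var_y[k]]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) stop("fewer than 3 complete pairs for ",
                    pairs$var_x[k], " vs ", pairs$var_y[k])
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(n = n, r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- cbind(pairs, do.call(rbind, res))
  out$subset <- subset
  if (is.null(n_family)) n_family <- nrow(out)
  out$significant <- !is.na(out$p) & out$p < alpha / n_family
  rownames(out) <- NULL
  out[, c("var_x", "var_y", "subset", "n", "r", "p", "significant")]
}
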