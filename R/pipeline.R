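#' Analysis configuration for the full pipeline
#'
#' @param hormones Analyte columns to regress edgewise (defaults to the
#'   all-session salivary measures plus serum estradiol).
#' @param B Permutations for the edgewise null (default 10000).
#' @param p_alpha Display threshold on permutation p (default 0.001).
#' @param q FDR level (default 0.05), used both for the edgewise strength
#'   mask and the per-session matrix thresholding.
#' @param use_wake_covariate Include time-since-waking as a covariate
#'   (default FALSE; the primary model is hormone-only).
#' @param threshold_for_regression Regress FDR-thresholded (rather than
#'   raw) coherence; default FALSE, since per-session zeroing censors the
#'   edge-hormone relation.
#' @param welch_window,welch_overlap Welch estimator parameters.
#' @param levels MODWT detail levels retained (default 3:6).
#' @return List of class `run_config`.
#' @export
run_config <- function(hormones = c("testosterone_saliva",
                                    "estradiol_serum",
                                    "cortisol_saliva"),
                       B = 10000L, p_alpha = 0.001, q = 0.05,
                       use_wake_covariate = FALSE,
                       threshold_for_regression = FALSE,
                       welch_window = 128L, welch_overlap = 0.5,
                       levels = 3:6) {
  stopifnot(B >= 100, p_alpha > 0, p_alpha <= 1, q > 0, q <= 1)
  structure(list(hormones = hormones, B = as.integer(B),
                 p_alpha = p_alpha, q = q,
                 use_wake_covariate = use_wake_covariate,
                 threshold_for_regression = threshold_for_regression,
                 welch_window = as.integer(welch_window),
                 welch_overlap = welch_overlap, levels = levels),
            class = "run_config")
}

# short deterministic fingerprint of a configuration
.config_hash <- function(...) {
  txt <- paste(unlist(lapply(list(...), deparse)), collapse = "")
  v <- utf8ToInt(txt)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Run the full simulate-clean-connect-regress-summarize pipeline
#'
#' Generates (or accepts) a synthetic study, cleans each session's regional
#' timeseries against its motion-derived nuisance design, estimates
#' band-limited coherence matrices, regresses every edge against each
#' configured hormone with a permutation null, derives signed nodal
#' strengths and network summaries, runs the hormone-by-network ANOVAs when
#' every network has at least two nodes, computes session graph metrics with
#' AM/PM comparisons, and (optionally) writes all tables plus a JSON report.
#'
#' @param config A [study_config()].
#' @param run A [run_config()].
#' @param seed Master seed; all stages derive their streams from it.
#' @param out_dir Output directory, or NULL to skip writing files.
#' @param study Optional pre-generated [simulate_study()] result (must match
#'   `config`); when NULL one is simulated from `seed`.
#' @return List with `study`, `matrices` (raw), `thresholded`, `maps`
#'   (per hormone, thresholded edgewise maps), `strengths`, `summaries`,
#'   `anova` (positive/negative, when estimable), `metrics`, `comparisons`,
#'   and `report` (the headline-numbers list written as JSON).
#' @export
run_pipeline <- function(config = study_config(), run = run_config(),
                         seed = config$seed, out_dir = NULL, study = NULL) {
  if (is.null(study)) study <- simulate_study(config, seed = seed)
  parc <- study$bold$parcellation
  ses <- study$hormones
  n_ses <- config$n_sessions

  # --- clean each session against its nuisance design
  cleaned <- vector("list", n_ses)
  for (s in seq_len(n_ses)) {
    design <- NULL
    if (!is.null(study$motion)) {
      fwd <- framewise_displacement(study$motion[[s]])
      design <- nuisance_design(motion = study$motion[[s]],
                                spikes = spike_regressors(fwd))
    }
    cleaned[[s]] <- clean_timeseries(study$bold$timeseries[[s]], design)
  }

  # --- per-session band-limited coherence matrices
  matrices <- lapply(cleaned, coherence_matrix,
                     levels = run$levels,
                     window = run$welch_window, overlap = run$welch_overlap)
  thresholded <- lapply(matrices, fdr_threshold_matrix, q = run$q)

  # --- edgewise permutation regression per hormone
  reg_src <- if (run$threshold_for_regression) thresholded else matrices
  edges_all <- edge_vector_set(reg_src)
  maps <- list()
  for (h in run$hormones) {
    hv <- ses[[h]]
    keep <- which(!is.na(hv))
    E <- edges_all[, keep, drop = FALSE]
    attr(E, "n_nodes") <- config$n_nodes
    cov <- if (run$use_wake_covariate)
      matrix(ses$wake_hours[keep], ncol = 1,
             dimnames = list(NULL, "wake_hours")) else NULL
    map <- permutation_null(E, hv[keep], covariates = cov, B = run$B,
                            seed = seed + 1000L + match(h, run$hormones))
    maps[[h]] <- threshold_map(map, p_alpha = run$p_alpha, q = run$q)
  }

  # --- nodal strengths, network summaries, ANOVAs
  strengths <- lapply(maps, nodal_strengths, parcellation = parc)
  summaries <- lapply(strengths, network_summary)
  anova_res <- NULL
  net_sizes <- table(parc$network)
  if (length(strengths) >= 2 && all(net_sizes >= 2)) {
    anova_res <- list(
      positive = hormone_network_anova(strengths, "positive"),
      negative = hormone_network_anova(strengths, "negative")
    )
  }

  # --- session-level graph metrics and AM/PM comparison
  metrics <- session_graph_metrics(thresholded, parc, config$schedule)
  safe_compare <- function(field) {
    tryCatch(am_pm_compare(metrics, field), error = function(e)
      list(t = NA_real_, df_welch = NA_real_, p = NA_real_,
           cohens_d = NA_real_, error = conditionMessage(e)))
  }
  comparisons <- list(efficiency = safe_compare("efficiency"),
                      participation = safe_compare("participation"))

  # --- headline report
  pct <- lapply(stats::setNames(nm = run$hormones), function(h)
    summarize_diurnal(ses, h)$pct_decrease)
  report <- list(
    config_hash = .config_hash(config, run),
    seed = seed,
    n_nodes = config$n_nodes,
    n_sessions = n_ses,
    n_edges = nrow(edges_all),
    pct_decrease = pct,
    fdr_survivors = lapply(maps, function(m) sum(m$strength_mask)),
    display_survivors = lapply(maps, function(m) sum(m$display_mask)),
    anova_residual_df = if (!is.null(anova_res))
      anova_res$positive$residual_df else NULL,
    efficiency_am_pm = comparisons$efficiency[c("t", "df_welch", "p")],
    participation_am_pm = comparisons$participation[c("t", "df_welch", "p")]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_session_table(ses, file.path(out_dir, "session_table.tsv"))
    write_parcellation(parc, file.path(out_dir, "parcellation.tsv"))
    for (h in names(maps))
      write_edgewise_map(maps[[h]],
                         file.path(out_dir, paste0("edgewise_", h, ".tsv")))
    for (h in names(strengths))
      utils::write.table(strengths[[h]],
                         file.path(out_dir, paste0("strengths_", h, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(metrics, file.path(out_dir, "session_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(study$bold$ground_truth$coupled_edges))
      jsonlite::write_json(study$bold$ground_truth,
                           file.path(out_dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }

  list(study = study, matrices = matrices, thresholded = thresholded,
       maps = maps, strengths = strengths, summaries = summaries,
       anova = anova_res, metrics = metrics, comparisons = comparisons,
       report = report)
}
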