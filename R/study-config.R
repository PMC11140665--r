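#' Default diurnal analyte parameters
#'
#' Morning (7 A.M.) and evening (8 P.M.) means and standard deviations for the
#' six assayed steroid-hormone measures, with their units and the medium
#' (saliva or serum) they are measured in. Serum analytes are available on a
#' subset of sessions only (one venipuncture per day on double-session days).
#'
#' @return A data.frame with one row per analyte and columns
#'   `analyte`, `mean_am`, `sd_am`, `mean_pm`, `sd_pm`, `units`, `serum`.
#' @export
default_hormone_params <- function() {
  data.frame(
    analyte = c("testosterone_saliva", "testosterone_serum",
                "free_testosterone", "estradiol_serum",
                "cortisol_saliva", "cortisol_serum"),
    mean_am = c(101.6, 513.4, 3.5, 23.8, 0.5, 15.9),
    sd_am   = c(10.20, 47.00, 0.40, 3.60, 0.10, 2.10),
    mean_pm = c(37.9, 286.4, 2.6, 14.5, 0.04, 2.6),
    sd_pm   = c(11.50, 79.00, 0.30, 2.90, 0.02, 0.90),
    units   = c("pg/ml", "ng/dl", "%FT", "pg/ml", "ug/dl", "ug/dl"),
    serum   = c(FALSE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Nine-network node counts of the reference 415-node parcellation
# (400 cortical regions grouped from a 17-network scheme into 8 networks,
# plus 15 subcortical nodes as their own network).
.network_counts <- c(
  Visual = 61, SomMot = 77, DorsAttn = 46, SalVentAttn = 47,
  Limbic = 26, Control = 52, DMN = 77, TempPar = 14, Subcortical = 15
)

#' Canonical network names
#' @return Character vector of the nine network labels.
#' @export
network_names <- function() names(.network_counts)

#' Study configuration for the synthetic dense-sampling design
#'
#' Describes a 40-session, 30-day diurnal study: 20 morning sessions at
#' 7 A.M. and 20 evening sessions at 8 P.M., with double sessions on days
#' 11-20 and serum assays on 30 of the 40 sessions. The default emulates the
#' reference design; every knob is overridable.
#'
#' @param n_nodes Number of parcellation nodes (default 415).
#' @param n_networks Number of networks (fixed at 9 for the default scheme).
#' @param n_sessions Number of sessions (default 40; must be even when the
#'   AM/PM design is balanced).
#' @param n_days Number of consecutive study days (default 30).
#' @param frames_per_session Frames per resting-state scan (default 1250,
#'   a 15 min scan at TR 0.72 s).
#' @param tr_seconds Repetition time in seconds (default 0.72).
#' @param hormone_params Per-analyte diurnal parameters as returned by
#'   [default_hormone_params()].
#' @param coupled_edges `NULL` or a data.frame with columns `i`, `j`
#'   (0-based node ids, `i < j`, node-disjoint across rows) and `beta`
#'   (coherence units per hormone SD).
#' @param coupling_analyte Analyte whose z-scored concentration drives the
#'   coupled edges (default `"testosterone_saliva"`, available at all
#'   sessions).
#' @param coupled_baseline Baseline band coherence of a coupled edge at
#'   hormone z = 0 (default 0.4).
#' @param baseline_block_coherence Within-network band coherence of
#'   uncoupled nodes (default 0.3).
#' @param global_coherence Between-network band coherence contributed by a
#'   whole-brain shared latent signal (default 0.1; must not exceed the
#'   within-network baseline).
#' @param noise_sd SD of broadband white measurement noise added on top of
#'   the unit-variance band-limited signal (default 0.1).
#' @param serum_sessions Integer session ids carrying serum assays; `NULL`
#'   (default) derives the 30-session schedule from the day layout.
#' @param seed Default random seed carried in the config.
#' @return An object of class `study_config` (a validated list).
#' @export
study_config <- function(n_nodes = 415L,
                         n_networks = 9L,
                         n_sessions = 40L,
                         n_days = 30L,
                         frames_per_session = 1250L,
                         tr_seconds = 0.72,
                         hormone_params = default_hormone_params(),
                         coupled_edges = NULL,
                         coupling_analyte = "testosterone_saliva",
                         coupled_baseline = 0.4,
                         baseline_block_coherence = 0.3,
                         global_coherence = 0.1,
                         noise_sd = 0.1,
                         serum_sessions = NULL,
                         seed = 1L) {
  stopifnot(n_nodes >= 2, n_networks == 9L, n_sessions >= 2, n_days >= 1,
            frames_per_session >= 8, tr_seconds > 0)
  if (n_sessions %% 2L != 0L)
    stop("n_sessions must be even for a balanced AM/PM design")
  if (any(hormone_params$sd_am < 0) || any(hormone_params$sd_pm < 0))
    stop("hormone SDs must be non-negative")
  if (!(coupling_analyte %in% hormone_params$analyte))
    stop("unknown coupling_analyte: ", coupling_analyte)
  if (coupled_baseline < 0 || coupled_baseline >= 1 ||
      baseline_block_coherence < 0 || baseline_block_coherence >= 1 ||
      global_coherence < 0 || global_coherence >= 1)
    stop("coherence parameters must lie in [0, 1)")
  if (global_coherence > baseline_block_coherence)
    stop("global_coherence must not exceed baseline_block_coherence")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(coupled_edges)) {
    stopifnot(is.data.frame(coupled_edges),
              all(c("i", "j", "beta") %in% names(coupled_edges)))
    if (any(coupled_edges$i >= coupled_edges$j))
      stop("coupled edges must satisfy i < j (0-based)")
    if (any(coupled_edges$j >= n_nodes) || any(coupled_edges$i < 0))
      stop("coupled-edge endpoints must be valid 0-based node ids")
    ep <- c(coupled_edges$i, coupled_edges$j)
    if (anyDuplicated(ep))
      stop("coupled edges must be node-disjoint")
    # keep the implied coherence inside [0,1] over +/- 3 hormone SD
    lo <- coupled_baseline - 3 * abs(coupled_edges$beta)
    hi <- coupled_baseline + 3 * abs(coupled_edges$beta)
    if (any(lo < -0.15) || any(hi > 1.15))
      warning("some coupled edges imply coherence well outside [0,1] at |z|=3; ",
              "values will be clipped during generation")
  }
  sched <- .session_schedule(n_sessions, n_days)
  if (is.null(serum_sessions)) serum_sessions <- sched$serum_sessions
  structure(list(
    n_nodes = as.integer(n_nodes),
    n_networks = 9L,
    n_sessions = as.integer(n_sessions),
    n_days = as.integer(n_days),
    frames_per_session = as.integer(frames_per_session),
    tr_seconds = tr_seconds,
    hormone_params = hormone_params,
    coupled_edges = coupled_edges,
    coupling_analyte = coupling_analyte,
    coupled_baseline = coupled_baseline,
    baseline_block_coherence = baseline_block_coherence,
    global_coherence = global_coherence,
    noise_sd = noise_sd,
    schedule = sched$table,
    serum_sessions = as.integer(serum_sessions),
    seed = as.integer(seed)
  ), class = "study_config")
}

# Day/time layout: single AM sessions early in the study, double sessions
# (AM + PM) in the middle block, single PM sessions late, so that exactly
# half of the sessions are AM.  Serum is drawn once per day (AM on half of
# the double days, PM on the other half).
.session_schedule <- function(n_sessions, n_days) {
  n_double <- n_sessions - n_days
  if (n_double < 0 || n_double > n_days)
    stop("n_sessions must lie in [n_days, 2*n_days]")
  n_single <- n_days - n_double
  d0 <- floor(n_single / 2)                     # leading single-AM days
  day <- integer(0); label <- character(0)
  for (d in seq_len(n_days)) {
    if (d <= d0) {
      day <- c(day, d); label <- c(label, "AM")
    } else if (d <= d0 + n_double) {
      day <- c(day, d, d); label <- c(label, "AM", "PM")
    } else {
      day <- c(day, d); label <- c(label, "PM")
    }
  }
  tab <- data.frame(session_id = seq_along(day), day = day,
                    time_label = label,
                    clock_time = ifelse(label == "AM", "07:00", "20:00"),
                    stringsAsFactors = FALSE)
  # one serum draw per day: on double days alternate AM/PM
  serum <- integer(0)
  for (d in unique(day)) {
    rows <- which(day == d)
    if (length(rows) == 1L) serum <- c(serum, rows)
    else serum <- c(serum, if (d %% 2 == 0) rows[label[rows] == "AM"]
                           else rows[label[rows] == "PM"])
  }
  list(table = tab, serum_sessions = sort(serum))
}

#' Build a synthetic parcellation lookup
#'
#' Assigns `n_nodes` nodes to the nine canonical networks in proportion to
#' the node counts of the reference 415-node scheme (largest-remainder
#' apportionment, with every network guaranteed at least two nodes when
#' `n_nodes >= 18`). This is a synthetic stand-in for a real atlas lookup.
#'
#' @param n_nodes Number of nodes.
#' @return A data.frame with columns `node_id` (0-based), `label`,
#'   `network`, `hemisphere`.
#' @export
build_parcellation <- function(n_nodes = 415L) {
  stopifnot(n_nodes >= 2)
  props <- .network_counts / sum(.network_counts)
  raw <- props * n_nodes
  cnt <- floor(raw)
  rem <- n_nodes - sum(cnt)
  if (rem > 0) {
    give <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[give] <- cnt[give] + 1
  }
  if (n_nodes >= 18) {
    while (any(cnt < 2)) {
      k <- which.min(cnt); big <- which.max(cnt)
      cnt[k] <- cnt[k] + 1; cnt[big] <- cnt[big] - 1
    }
  }
  network <- rep(names(.network_counts), times = cnt)   # zero-count networks drop out at small n
  data.frame(
    node_id = seq_len(n_nodes) - 1L,
    label = sprintf("%s_%03d", network, unlist(lapply(cnt, seq_len))),
    network = network,
    hemisphere = rep_len(c("L", "R"), n_nodes),
    stringsAsFactors = FALSE
  )
}
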