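#' Simulate diurnal hormone concentrations for a study
#'
#' Draws one concentration per analyte per session from the configured
#' morning/evening normal distributions, truncated at zero by redrawing
#' (clipping would bias the mean upward for analytes whose evening mean sits
#' close to zero, e.g. salivary cortisol). Serum analytes are filled only on
#' the serum sessions. A time-since-waking covariate is added: roughly one
#' hour for 7 A.M. sessions and fourteen hours for 8 P.M. sessions.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; defaults to the config's seed.
#' @return A session table (data.frame): `session_id`, `day`, `time_label`,
#'   `clock_time`, `wake_hours`, then one column per analyte.
#' @export
simulate_hormones <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  set.seed(seed)
  tab <- config$schedule
  n <- nrow(tab)
  am <- tab$time_label == "AM"
  tab$wake_hours <- ifelse(am, stats::rnorm(n, 1, 0.15),
                               stats::rnorm(n, 14, 0.5))
  hp <- config$hormone_params
  for (k in seq_len(nrow(hp))) {
    mu <- ifelse(am, hp$mean_am[k], hp$mean_pm[k])
    sg <- ifelse(am, hp$sd_am[k], hp$sd_pm[k])
    x <- .rnorm_trunc0(n, mu, sg)
    if (hp$serum[k]) x[!(tab$session_id %in% config$serum_sessions)] <- NA_real_
    tab[[hp$analyte[k]]] <- x
  }
  tab
}

# normal draw truncated at zero by redraw; exact when sd = 0
.rnorm_trunc0 <- function(n, mu, sg) {
  x <- stats::rnorm(n, mu, sg)
  bad <- which(x < 0)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mu[bad], sg[bad])
    bad <- bad[x[bad] < 0]
    guard <- guard + 1L
  }
  x[x < 0] <- 0
  x
}

# unit-variance Gaussian noise with spectral energy confined to [f_lo, f_hi],
# synthesized in the frequency domain
.bandlimited_noise <- function(n, tr, f_lo, f_hi) {
  freqs <- seq(0, n - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)        # fold to [0, Nyquist]
  keep <- freqs >= f_lo & freqs <= f_hi
  z <- stats::fft(stats::rnorm(n))
  z[!keep] <- 0
  x <- Re(stats::fft(z, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  (x - mean(x)) / s
}

#' Simulate regional BOLD-like timeseries with hormone-coupled edges
#'
#' Each network shares a band-limited latent signal (energy in
#' 0.01-0.17 Hz) and all nodes additionally share a whole-brain global
#' latent; the mixing weights are chosen so that the realized band
#' magnitude-squared coherence equals `baseline_block_coherence` within a
#' network and `global_coherence` between networks. For each
#' coupled edge (i, j) with slope `beta`, the pair shares its own latent
#' with session-specific mixing weight `c_s^(1/4)`, where
#' `c_s = clip(coupled_baseline + beta * z_s, 0, 0.95)` and `z_s` is the
#' session's z-scored coupling-analyte concentration — so the realized band
#' coherence of that edge varies (approximately linearly) with the hormone.
#' Broadband white noise of SD `noise_sd` is added, and series are placed on
#' a BOLD-like scale (mean 1000).
#'
#' @param config A [study_config()] (coupled nodes must be node-disjoint).
#' @param hormones Session table from [simulate_hormones()].
#' @param seed Integer seed.
#' @param parcellation Optional parcellation; defaults to
#'   [build_parcellation()] at the config's size.
#' @return A list with `timeseries` (list of nodes x frames matrices, one
#'   per session, with `tr_seconds` attribute), `ground_truth` (a list with
#'   `coupled_edges`, `hormone_z`, `coupling_analyte`, `clip_count`), and
#'   `parcellation`.
#' @export
simulate_bold <- function(config, hormones, seed = config$seed + 1L,
                          parcellation = NULL) {
  stopifnot(inherits(config, "study_config"),
            nrow(hormones) == config$n_sessions)
  n_seg_min <- 4L
  if (config$frames_per_session < n_seg_min * 32L)
    stop("frames_per_session too short for spectral estimation")
  if (is.null(parcellation)) parcellation <- build_parcellation(config$n_nodes)
  stopifnot(nrow(parcellation) == config$n_nodes)
  set.seed(seed)

  h <- hormones[[config$coupling_analyte]]
  if (anyNA(h))
    stop("coupling analyte must be observed at every session; choose a ",
         "salivary analyte or restrict sessions")
  z <- as.numeric(scale(h))

  nets <- parcellation$network
  net_levels <- unique(nets)
  n <- config$n_nodes
  nf <- config$frames_per_session
  tr <- config$tr_seconds
  f_lo <- 1 / (tr * 2^7); f_hi <- 1 / (tr * 2^3)

  ce <- config$coupled_edges
  coupled_nodes <- if (is.null(ce)) integer(0) else c(ce$i, ce$j) + 1L
  # mixing weights: a node is a_g * global + a_n * network latent + private
  # noise, giving between-network MSC a_g^4 = global_coherence and
  # within-network MSC (a_g^2 + a_n^2)^2 = baseline_block_coherence
  ag2 <- sqrt(config$global_coherence)
  an2 <- sqrt(config$baseline_block_coherence) - ag2
  a_glob <- sqrt(ag2)
  a_net <- sqrt(an2)
  a_priv <- sqrt(1 - ag2 - an2)
  clip_count <- 0L

  ts_list <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    lat <- sapply(net_levels, function(nm) .bandlimited_noise(nf, tr, f_lo, f_hi))
    glob <- .bandlimited_noise(nf, tr, f_lo, f_hi)
    X <- matrix(0, n, nf)
    for (i in seq_len(n)) {
      if (i %in% coupled_nodes) next
      e <- .bandlimited_noise(nf, tr, f_lo, f_hi)
      X[i, ] <- a_glob * glob + a_net * lat[, match(nets[i], net_levels)] +
        a_priv * e
    }
    if (!is.null(ce)) {
      for (k in seq_len(nrow(ce))) {
        c_s <- config$coupled_baseline + ce$beta[k] * z[s]
        if (c_s < 0 || c_s > 0.95) {
          clip_count <- clip_count + 1L
          c_s <- min(max(c_s, 0), 0.95)
        }
        a <- c_s^0.25
        u <- .bandlimited_noise(nf, tr, f_lo, f_hi)
        for (node in c(ce$i[k], ce$j[k]) + 1L) {
          e <- .bandlimited_noise(nf, tr, f_lo, f_hi)
          X[node, ] <- a * u + sqrt(1 - a^2) * e
        }
      }
    }
    X <- X + config$noise_sd * matrix(stats::rnorm(n * nf), n, nf)
    X <- 50 * X + 1000                      # BOLD-like units
    attr(X, "tr_seconds") <- tr
    attr(X, "session_id") <- s
    ts_list[[s]] <- X
  }
  if (clip_count > 0L)
    message("coupled-edge coherence clipped to [0, 0.95] in ",
            clip_count, " session-edge draws")
  list(
    timeseries = ts_list,
    ground_truth = list(
      coupled_edges = ce,
      hormone_z = z,
      coupling_analyte = config$coupling_analyte,
      clip_count = clip_count
    ),
    parcellation = parcellation
  )
}

#' Simulate head-motion traces and session mood scores
#'
#' Motion is a six-parameter random walk (translations in mm, rotations in
#' radians) whose step size sets the expected framewise displacement; evening
#' sessions can be given larger amplitude than morning ones. A fixed number
#' of sessions receive one to three large spikes (0.6-0.9 mm) so that spike
#' regressors are exercised. Mood scores are drawn within plausible scale
#' ranges and are independent of the hormones.
#'
#' @param config A [study_config()].
#' @param seed Integer seed.
#' @param fwd_target_am,fwd_target_pm Expected mean FWD (mm) for AM / PM
#'   sessions (defaults 0.006 and 0.010, an "exceedingly minimal" regime).
#' @param n_spike_sessions Number of sessions containing at least one
#'   >500-micron spike (default 17).
#' @return A list with `motion` (list of frames x 6 matrices) and `mood`
#'   (data.frame of per-session scale scores).
#' @export
simulate_motion_mood <- function(config, seed = config$seed + 2L,
                                 fwd_target_am = 0.006,
                                 fwd_target_pm = 0.010,
                                 n_spike_sessions = min(17L, config$n_sessions)) {
  stopifnot(inherits(config, "study_config"),
            n_spike_sessions <= config$n_sessions)
  set.seed(seed)
  tab <- config$schedule
  nf <- config$frames_per_session
  # FWD sums |steps| of 3 translations plus 50 * |steps| of 3 rotations;
  # E|N(0, s)| = s * sqrt(2/pi), so 6 equal contributions give the target.
  step_from_target <- function(target) target / (6 * sqrt(2 / pi))
  spike_sessions <- sort(sample(config$n_sessions, n_spike_sessions))
  motion <- vector("list", config$n_sessions)
  for (s in seq_len(config$n_sessions)) {
    target <- if (tab$time_label[s] == "AM") fwd_target_am else fwd_target_pm
    st <- step_from_target(target)
    steps <- cbind(matrix(stats::rnorm(3 * nf, 0, st), nf, 3),
                   matrix(stats::rnorm(3 * nf, 0, st / 50), nf, 3))
    steps[1, ] <- 0
    if (s %in% spike_sessions) {
      k <- sample(1:3, 1)
      at <- sample(2:nf, k)
      steps[at, 1] <- steps[at, 1] + stats::runif(k, 0.6, 0.9) *
        sample(c(-1, 1), k, replace = TRUE)
    }
    m <- apply(steps, 2, cumsum)
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_x", "rot_y", "rot_z")
    motion[[s]] <- m
  }
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  n <- config$n_sessions
  mood <- data.frame(
    session_id = tab$session_id,
    stress = clamp(round(stats::rnorm(n, 12, 3)), 0, 40),
    anxiety = clamp(round(stats::rnorm(n, 32, 5)), 20, 80),
    poms_total = clamp(round(stats::rnorm(n, 10, 8)), -32, 200),
    vigor = clamp(round(stats::rnorm(n, 18, 4)), 0, 32),
    fatigue = clamp(round(stats::rnorm(n, 6, 3)), 0, 28),
    aggression = clamp(round(stats::rnorm(n, 60, 8)), 29, 145),
    sleep_quality = clamp(round(stats::rnorm(n, 4, 1.5)), 0, 21)
  )
  list(motion = motion, mood = mood, spike_sessions = spike_sessions)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper bundling [simulate_hormones()], [simulate_bold()] and
#' [simulate_motion_mood()] under one seed.
#'
#' @param config A [study_config()].
#' @param seed Master seed; the three generators use `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param motion Logical; also simulate motion and mood (default TRUE).
#' @return List with `config`, `hormones`, `bold` (timeseries +
#'   ground_truth + parcellation) and optionally `motion`, `mood`.
#' @export
simulate_study <- function(config = study_config(), seed = config$seed,
                           motion = TRUE) {
  hormones <- simulate_hormones(config, seed)
  bold <- simulate_bold(config, hormones, seed + 1L)
  out <- list(config = config, hormones = hormones, bold = bold)
  if (motion) {
    mm <- simulate_motion_mood(config, seed + 2L)
    out$motion <- mm$motion
    out$mood <- mm$mood
    out$spike_sessions <- mm$spike_sessions
  }
  out
}
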