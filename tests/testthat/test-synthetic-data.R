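test_that("hormone draws hit the configured diurnal means exactly when SDs are zero", {
  cfg <- study_config(n_nodes = 12, hormone_params = zero_sd_params())
  h <- simulate_hormones(cfg, seed = 1)
  am <- h$time_label == "AM"
  expect_true(all(h$testosterone_saliva[am] == 101.6))
  expect_true(all(h$testosterone_saliva[!am] == 37.9))
  expect_true(all(h$cortisol_saliva[am] == 0.5))
  expect_true(all(h$cortisol_saliva[!am] == 0.04))
  # serum analytes observed on exactly 30 of 40 sessions, half AM half PM
  obs <- !is.na(h$estradiol_serum)
  expect_equal(sum(obs), 30)
  expect_equal(sum(obs & am), 15)
  # constant analyte: zero percent decrease
  hp <- zero_sd_params()
  hp$mean_pm <- hp$mean_am
  cfg2 <- study_config(n_nodes = 12, hormone_params = hp)
  h2 <- simulate_hormones(cfg2, seed = 1)
  for (a in hp$analyte[!hp$serum])
    expect_equal(summarize_diurnal(h2, a)$pct_decrease, 0)
})

test_that("empirical hormone means converge on the configured values (Monte Carlo)", {
  cfg <- study_config(n_nodes = 12, n_sessions = 10000L, n_days = 5000L)
  h <- simulate_hormones(cfg, seed = 3)
  am <- h$cortisol_saliva[h$time_label == "AM"]
  se <- 0.10 / sqrt(length(am))
  expect_lt(abs(mean(am) - 0.5), 2 * se)
  # zero-truncation keeps concentrations non-negative for the near-zero analyte
  expect_true(all(h$cortisol_saliva >= 0, na.rm = TRUE))
})

test_that("hormone configuration errors are caught", {
  hp <- default_hormone_params()
  hp$sd_am[1] <- -1
  expect_error(study_config(hormone_params = hp), "non-negative")
  expect_error(study_config(n_sessions = 39), "even")
  expect_error(study_config(coupled_edges = data.frame(i = 0L, j = 0L, beta = 0.1)),
               "i < j")
  expect_error(study_config(coupled_edges = data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                                       beta = c(0.1, 0.1))),
               "node-disjoint")
})

test_that("coupled-edge coherence tracks the hormone (direct cross-spectrum oracle)", {
  ce <- data.frame(i = 0L, j = 1L, beta = 0.18)
  cfg <- study_config(n_nodes = 6, frames_per_session = 640,
                      coupled_edges = ce, noise_sd = 0.02, seed = 5)
  sim <- simulate_study(cfg, motion = FALSE)
  z <- sim$bold$ground_truth$hormone_z
  # oracle: smoothed-periodogram coherency from stats::spec.pgram,
  # band-averaged, independent of the package's Welch estimator
  band <- modwt_band_limits(cfg$tr_seconds)
  oracle_coh <- vapply(sim$bold$timeseries, function(X) {
    sp <- spec.pgram(ts(cbind(X[1, ], X[2, ]), deltat = cfg$tr_seconds),
                     spans = 15, taper = 0.1, detrend = TRUE, plot = FALSE)
    mean(sp$coh[sp$freq >= band[1] & sp$freq <= band[2]])
  }, numeric(1))
  top <- order(z, decreasing = TRUE)[1:5]
  bot <- order(z)[1:5]
  expect_gt(mean(oracle_coh[top]), mean(oracle_coh[bot]))
})

test_that("with no coupling, no edge's coherence carries a hormone slope signal", {
  cfg <- tiny_config(n_nodes = 8, frames = 640, seed = 11, n_sessions = 20,
                     n_days = 15)
  sim <- simulate_study(cfg, motion = FALSE)
  mats <- lapply(sim$bold$timeseries, coherence_matrix, window = 64L)
  E <- edge_vector_set(mats)
  map <- edgewise_regression(E, sim$hormones$testosterone_saliva)
  # standardized slopes behave like null correlations at n = 20
  expect_lt(max(abs(map$beta_z)), 0.9)
  expect_lt(abs(mean(map$beta_z)), 0.3)
})

test_that("generation is bit-identical under a fixed seed and errors on short scans", {
  cfg <- tiny_config(n_nodes = 5, frames = 640, seed = 2, n_sessions = 4,
                     n_days = 4)
  s1 <- simulate_study(cfg, motion = TRUE)
  s2 <- simulate_study(cfg, motion = TRUE)
  expect_identical(s1$hormones, s2$hormones)
  expect_identical(s1$bold$timeseries, s2$bold$timeseries)
  expect_identical(s1$motion, s2$motion)
  cfg_short <- study_config(n_nodes = 5, frames_per_session = 100,
                            n_sessions = 4, n_days = 4)
  expect_error(simulate_bold(cfg_short, simulate_hormones(cfg_short, 1)),
               "too short")
})

test_that("motion generator obeys amplitude controls and the spike-session count", {
  cfg <- tiny_config(n_nodes = 5, frames = 200, n_sessions = 40, n_days = 30)
  mm0 <- simulate_motion_mood(cfg, seed = 4, fwd_target_am = 0,
                              fwd_target_pm = 0, n_spike_sessions = 0)
  expect_true(all(framewise_displacement(mm0$motion[[1]]) == 0))
  mm <- simulate_motion_mood(cfg, seed = 4, fwd_target_am = 0.004,
                             fwd_target_pm = 0.012, n_spike_sessions = 17)
  fwd_mean <- vapply(mm$motion, function(m) mean(framewise_displacement(m)),
                     numeric(1))
  am <- cfg$schedule$time_label == "AM"
  expect_gt(mean(fwd_mean[!am]), mean(fwd_mean[am]))
  flagged <- vapply(mm$motion, function(m)
    any(framewise_displacement(m) > 0.5), logical(1))
  expect_equal(sum(flagged), 17)
  mm2 <- simulate_motion_mood(cfg, seed = 4, fwd_target_am = 0.004,
                              fwd_target_pm = 0.012, n_spike_sessions = 17)
  expect_identical(mm$motion, mm2$motion)
  # mood scores stay within scale ranges
  expect_true(all(mm$mood$stress >= 0 & mm$mood$stress <= 40))
  expect_true(all(mm$mood$anxiety >= 20 & mm$mood$anxiety <= 80))
})

test_that("parcellation apportionment matches the reference scheme", {
  p <- build_parcellation(415)
  expect_equal(nrow(p), 415)
  cnt <- table(p$network)
  expect_equal(length(cnt), 9)
  expect_equal(unname(cnt[["Subcortical"]]), 15)
  expect_equal(unname(cnt[["DMN"]]), 77)
  p40 <- build_parcellation(40)
  expect_equal(nrow(p40), 40)
  expect_true(all(table(p40$network) >= 2))
})
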