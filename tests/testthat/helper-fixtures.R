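# Small study configurations used across tests.

tiny_config <- function(n_nodes = 12L, frames = 640L, coupled_edges = NULL,
                        seed = 7L, n_sessions = 40L, n_days = 30L) {
  study_config(n_nodes = n_nodes, frames_per_session = frames,
               coupled_edges = coupled_edges, seed = seed,
               n_sessions = n_sessions, n_days = n_days)
}

# hormone parameters with zero SDs (deterministic draws at the means)
zero_sd_params <- function() {
  hp <- default_hormone_params()
  hp$sd_am[] <- 0
  hp$sd_pm[] <- 0
  hp
}

# build a minimal thresholded edgewise map from hand-set masked t values
manual_map <- function(n_nodes, t_vec, mask = !is.na(t_vec) & t_vec != 0) {
  structure(list(t = t_vec, beta_z = t_vec, p = rep(0.5, length(t_vec)),
                 n_nodes = n_nodes, strength_mask = mask,
                 display_mask = mask),
            class = "edgewise_map")
}
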