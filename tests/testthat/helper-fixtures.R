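# Shared fixtures: small models and synthetic sessions built in code.

# a fixed, well-conditioned 2x2 model with nonzero cross-population noise
fixture_model <- function(c_xy = 0.2) {
  gaussian_pair_model(mu_x = c(1.2, 0.4), mu_y = c(0.8, -0.6),
                      sigma = c(1, 1.5, 0.8, 1.2),
                      c_x = 0.3, c_y = 0.4, c_xy = c_xy)
}

# independent best-threshold classifier: try every midpoint threshold and
# both orientations by direct classification (O(T^2) oracle)
naive_best_threshold <- function(v, lab) {
  lv <- sort(unique(as.character(lab)))
  u <- sort(unique(v))
  thr <- c(min(v) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, max(v) + 1)
  best <- 0
  for (t in thr) for (o in c(1L, -1L)) {
    pred_b <- if (o > 0) v > t else v < t
    best <- max(best, mean((as.character(lab) == lv[2]) == pred_b))
  }
  best
}

# small two-stimulus synthetic session with strong, fully coupled signal
# and no cross-region noise latent (the favorable regime)
fixture_session_clean <- function(seed = 5, n = 12, trials = 42) {
  cfg <- synthetic_config(
    n_upstream = n, n_cortex = n, n_stimuli = 2,
    trials_per_stimulus = trials, tuning_strength = 1, signal_coupling = 1,
    shared_noise_loading = list(upstream = 0, cortex = 0),
    local_noise_loading = list(upstream = 0.3, cortex = 0.3), seed = seed
  )
  generate_session(cfg)
}

# session dominated by a heterogeneous cross-region noise latent
fixture_session_noisy <- function(seed = 6, n = 16, trials = 42) {
  set.seed(seed + 1000)
  cfg <- synthetic_config(
    n_upstream = n, n_cortex = n, n_stimuli = 2,
    trials_per_stimulus = trials, tuning_strength = 0.5, signal_coupling = 0.5,
    shared_noise_loading = list(upstream = ifelse(stats::runif(n) < 0.5, 0, 1),
                                cortex = ifelse(stats::runif(n) < 0.5, 0, 1)),
    local_noise_loading = list(upstream = 0.2, cortex = 0.2), seed = seed
  )
  generate_session(cfg)
}
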