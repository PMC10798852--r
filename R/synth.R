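#' Configuration for the dual-region Poisson session generator
#'
#' Defines a synthetic dual-region recording: per trial, each neuron's
#' log-rate is the sum of a baseline, its stimulus tuning, its loading on a
#' cross-region shared latent, and a region-local latent; spike counts are
#' Poisson with that rate over the response window. Cortical tuning is a
#' mixture of the upstream signal axis (fraction `signal_coupling`) and
#' independent tuning, so signal genuinely propagates from the upstream
#' region into cortex.
#'
#' @param n_upstream,n_cortex Neurons per region.
#' @param n_stimuli Number of distinct stimuli.
#' @param trials_per_stimulus Trials per stimulus (>= 2).
#' @param window_ms Response window in milliseconds (default 250).
#' @param baseline_log_rate Log firing rate (Hz) baseline; default
#'   `log(10)` (10 spikes/s).
#' @param tuning_strength SD of the stimulus-driven log-rate modulation
#'   (>= 0).
#' @param shared_noise_loading Per-neuron loadings onto the cross-region
#'   latent: a list with elements `upstream` and `cortex`, each a scalar
#'   (recycled) or a length-`n` vector.
#' @param local_noise_loading Scalar loading onto each region's private
#'   latent: list with `upstream` and `cortex` scalars.
#' @param signal_coupling Fraction in `[0, 1]` of cortical tuning inherited
#'   from the upstream signal axis.
#' @param seed Integer seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_upstream, n_cortex, n_stimuli = 2L,
                             trials_per_stimulus = 42L, window_ms = 250,
                             baseline_log_rate = log(10),
                             tuning_strength = 1,
                             shared_noise_loading = list(upstream = 0, cortex = 0),
                             local_noise_loading = list(upstream = 0.2, cortex = 0.2),
                             signal_coupling = 0.8, seed = 1L) {
  stopifnot(n_upstream >= 2L, n_cortex >= 2L, n_stimuli >= 2L,
            trials_per_stimulus >= 2L, window_ms > 0, tuning_strength >= 0,
            signal_coupling >= 0, signal_coupling <= 1)
  expand <- function(v, n, nm) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop("`", nm, "` loading must be scalar or length ", n,
                             call. = FALSE)
    v
  }
  shared_noise_loading$upstream <- expand(shared_noise_loading$upstream,
                                          n_upstream, "upstream")
  shared_noise_loading$cortex <- expand(shared_noise_loading$cortex,
                                        n_cortex, "cortex")
  structure(list(n_upstream = n_upstream, n_cortex = n_cortex,
                 n_stimuli = n_stimuli,
                 trials_per_stimulus = trials_per_stimulus,
                 window_ms = window_ms,
                 baseline_log_rate = baseline_log_rate,
                 tuning_strength = tuning_strength,
                 shared_noise_loading = shared_noise_loading,
                 local_noise_loading = local_noise_loading,
                 signal_coupling = signal_coupling, seed = seed),
            class = "synthetic_config")
}

#' Generate a synthetic dual-region Poisson session
#'
#' Draws a [recording_session()] from a [synthetic_config()], together with
#' the ground truth used to build it (stimulus signal values, tuning
#' matrices, latent loadings) for planted-structure assertions.
#'
#' The generative model, per trial `t` with stimulus `s`:
#' `log rate_i = baseline + tuning_i(s) + shared_i * z_t + local * u_t^region`
#' with `z_t`, `u_t` standard normal; counts are
#' `Poisson(exp(log rate) * window)`. The upstream tuning is rank-1 across
#' stimuli (`tuning_i(s) = strength * b_i * g(s)`, a 1D signal axis);
#' cortical tuning mixes the same signal axis with independent per-neuron
#' tuning in proportion `signal_coupling : 1 - signal_coupling`. Log-rates
#' are clipped to `[-10, 6]` to guard against overflow (a message notes
#' when clipping occurs).
#'
#' @param config A [synthetic_config()].
#' @return List with `session` (a [recording_session()]) and `ground_truth`
#'   (list: `signal`, `tuning_upstream`, `tuning_cortex`, loadings).
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nu <- config$n_upstream; nc <- config$n_cortex
  S <- config$n_stimuli; Tr <- config$trials_per_stimulus
  Tn <- S * Tr
  stim_levels <- sprintf("s%02d", seq_len(S))
  stimulus <- rep(stim_levels, each = Tr)
  # 1D stimulus signal, standardized across stimuli
  g <- stats::rnorm(S)
  g <- (g - mean(g)) / max(stats::sd(g), 1e-12)
  b_up <- stats::rnorm(nu)
  b_cx <- stats::rnorm(nc)
  tune_up <- config$tuning_strength * outer(b_up, g)            # nu x S
  indep <- matrix(stats::rnorm(nc * S), nc, S)
  tune_cx <- config$tuning_strength *
    (config$signal_coupling * outer(b_cx, g) +
     (1 - config$signal_coupling) * indep)                      # nc x S
  z <- stats::rnorm(Tn)
  u_up <- stats::rnorm(Tn)
  u_cx <- stats::rnorm(Tn)
  s_idx <- match(stimulus, stim_levels)
  log_rate_up <- config$baseline_log_rate + t(tune_up[, s_idx, drop = FALSE]) +
    tcrossprod(z, config$shared_noise_loading$upstream) +
    u_up * config$local_noise_loading$upstream
  log_rate_cx <- config$baseline_log_rate + t(tune_cx[, s_idx, drop = FALSE]) +
    tcrossprod(z, config$shared_noise_loading$cortex) +
    u_cx * config$local_noise_loading$cortex
  lr <- cbind(log_rate_up, log_rate_cx)
  n_clip <- sum(lr < -10 | lr > 6)
  if (n_clip > 0L) {
    message("clipped ", n_clip, " log-rates to [-10, 6]")
    lr <- pmin(pmax(lr, -10), 6)
  }
  lambda <- exp(lr) * (config$window_ms / 1000)
  counts <- matrix(stats::rpois(length(lambda), lambda), nrow = Tn)
  colnames(counts) <- c(sprintf("u%03d", seq_len(nu)), sprintf("c%03d", seq_len(nc)))
  session <- recording_session(
    counts, region = c(rep("upstream", nu), rep("cortex", nc)),
    stimulus = stimulus, window_ms = config$window_ms,
    id = paste0("synthetic-seed", config$seed)
  )
  list(session = session,
       ground_truth = list(signal = g,
                           tuning_upstream = tune_up, tuning_cortex = tune_cx,
                           shared_noise_loading = config$shared_noise_loading,
                           local_noise_loading = config$local_noise_loading))
}

#' Preset generator configurations emulating the two recording styles
#'
#' `"olfactory"`: 27 upstream (olfactory-bulb-like) and 48 cortical
#' (piriform-like) neurons, 6 odor stimuli, 15 trials each.
#' `"visual"`: 61 upstream (LGN-like) and 245 cortical (V1-like) neurons, a
#' 6-orientation x 5-spatial-frequency grating grid (30 stimuli), 42 trials
#' each. Both use a 250 ms response window. Session stimulus labels are
#' generic (`s01`, `s02`, ...); for the visual preset the
#' orientation-by-frequency grid behind each label is attached as the
#' `stimulus_grid` attribute of the returned config.
#'
#' @param name `"visual"` or `"olfactory"`.
#' @param seed Integer seed stored in the config.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A [synthetic_config()].
#' @export
preset <- function(name = c("visual", "olfactory"), seed = 1L, ...) {
  name <- match.arg(name)
  args <- switch(name,
    olfactory = list(n_upstream = 27L, n_cortex = 48L, n_stimuli = 6L,
                     trials_per_stimulus = 15L),
    visual = list(n_upstream = 61L, n_cortex = 245L, n_stimuli = 30L,
                  trials_per_stimulus = 42L)
  )
  defaults <- list(window_ms = 250, tuning_strength = 0.8,
                   signal_coupling = 0.7,
                   shared_noise_loading = list(upstream = 0.2, cortex = 0.2),
                   local_noise_loading = list(upstream = 0.3, cortex = 0.3),
                   seed = seed)
  over <- list(...)
  cfg <- utils::modifyList(c(args, defaults), over)
  out <- do.call(synthetic_config, cfg)
  if (name == "visual") {
    attr(out, "stimulus_grid") <- expand.grid(
      orientation = c(0, 30, 60, 90, 120, 150),
      spatial_frequency = c(0.02, 0.04, 0.08, 0.16, 0.32)
    )
  }
  attr(out, "preset") <- name
  out
}
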