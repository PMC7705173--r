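# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# deterministic square-wave gait: 10 s, 1 s cycles, no jitter
ideal_params <- function() {
  gait_cycle_params(cycle_duration = 1, jitter_sd = 0,
                    stance_fraction = 0.6, leg_phase_offset = 0.5,
                    duration = 10, sampling_rate = 1000)
}

ideal_footswitch <- function() {
  cached("ideal_fw", simulate_footswitch(ideal_params(), seed = 7))
}

# short jittered walking session for feature/decoder tests
short_session <- function() {
  cached("short_session", {
    p <- gait_cycle_params(duration = 60, sampling_rate = 1000)
    simulate_session(p, seed = 101)
  })
}

short_emg_features <- function() {
  cached("short_emg_feats", {
    s <- short_session()
    emg_window_features(s$emg, labels = s$labels)
  })
}

short_eeg_features <- function() {
  cached("short_eeg_feats", {
    s <- short_session()
    eeg_window_features(s$eeg, labels = s$labels)
  })
}

# toy separable 2-class sequence data for decoder tests: feature = class
# indicator + noise
toy_decoder_data <- function(n = 600, seed = 5) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = 50)[1 + (seq_len(n) - 1) %% 100]
  x <- cbind(ifelse(y == "A", 1, -1) + rnorm(n, 0, 0.3),
             rnorm(n, 0, 0.3))
  list(features = x, labels = y)
}

# random valid column-normalized conditional table
random_conditionals <- function(m) {
  tab <- matrix(stats::rexp(m * m) + 1e-6, m, m)
  sweep(tab, 2, colSums(tab), "/")
}
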