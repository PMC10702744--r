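# Shared fixtures: everything is built in code at test time.

# Two-node montage for miniature models.
mini_montage <- function() montage_graph(rbind(c("O1", "O2")), c("O1", "O2"))

# Miniature configuration: 2 nodes, 16 feature channels, 5 input bands.
mini_config <- function(...) {
  model_config(in_bands = 5L, n_nodes = 2L, C = 16L, n_blocks = 2L,
               seed = 3L, ...)
}

# Single-band scheme covering the whole 1-50 Hz passband, for closed-form
# differential-entropy checks on unit-variance band-limited noise.
full_passband_scheme <- function() {
  structure(list(name = "full", bands = matrix(c(1, 50), 1,
                                               dimnames = list("full",
                                                               c("low", "high"))),
                 right_closed = TRUE),
            class = "band_scheme")
}

# Unit-variance Gaussian noise band-limited to [low, high]: uses the
# package's exact FFT-mask synthesis.
unit_band_noise_window <- function(n_channels = 17, fs = 200, seconds = 8,
                                   low = 1, high = 50, seed = 1) {
  with_seed_local(seed, {
    sig <- t(vapply(seq_len(n_channels),
                    function(i) amdgcn:::band_noise(fs * seconds, fs, low, high),
                    numeric(fs * seconds)))
    eeg_window(sig, fs = fs,
               channel_names = canonical_channels()[seq_len(n_channels)],
               window_seconds = seconds)
  })
}

# seed an expression without touching the caller's RNG
with_seed_local <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# forward-pass internals (tests may inspect caches and maps)
fw <- function(...) amdgcn:::amdgcn_forward(...)
loss_grad <- function(...) amdgcn:::amdgcn_loss_grad(...)
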