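# Shared fixtures, built once per test run and cached in-process.

.fixtures <- new.env(parent = emptyenv())

# preprocessed, segmented windows from a small synthetic dataset
small_windows <- function(n_rounds = 2, seed = 42) {
  key <- sprintf("w_%d_%d", n_rounds, seed)
  if (is.null(.fixtures[[key]])) {
    cfg <- protocol_config(n_rounds = n_rounds, seed = seed)
    recs <- lapply(generate_dataset(config = cfg), preprocess_recording)
    .fixtures[[key]] <- segment_dataset(recs)
  }
  .fixtures[[key]]
}

# per-movement epoch RMS on one channel of a raw round
epoch_rms <- function(recording, label, channel,
                      from_ms = 1500, to_ms = 2650) {
  fs <- recording$sampling_rate_hz
  t0 <- recording$events$prompt_time_s[recording$events$label == label]
  idx <- round(t0 * fs) + seq(round(from_ms / 1000 * fs),
                              round(to_ms / 1000 * fs))
  sqrt(mean(recording$samples[idx, channel]^2))
}
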