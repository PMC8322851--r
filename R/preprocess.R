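#' Filtering specification for fEMG preprocessing
#'
#' The preprocessing chain is an IIR notch at the mains frequency followed by
#' a second-order Butterworth band-pass (default 10-450 Hz), applied causally
#' per channel so that the identical code path serves offline files and
#' online streaming. A zero-phase variant (forward-backward) is available for
#' offline use only.
#'
#' @param mains_hz mains interference frequency in Hz (default 50).
#' @param notch_quality dimensionless quality factor Q of the notch
#'   (default 30; bandwidth = mains_hz / Q).
#' @param band_low_hz band-pass lower edge in Hz (default 10).
#' @param band_high_hz band-pass upper edge in Hz (default 450).
#' @param order Butterworth band-pass order (default 2).
#' @param causal logical; `TRUE` (default) filters forward-only,
#'   `FALSE` selects zero-phase forward-backward filtering (offline only).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(mains_hz = 50, notch_quality = 30,
                        band_low_hz = 10, band_high_hz = 450,
                        order = 2L, causal = TRUE) {
  stopifnot(mains_hz > 0, notch_quality > 0, order >= 1,
            band_low_hz > 0, band_high_hz > band_low_hz)
  structure(list(mains_hz = mains_hz, notch_quality = notch_quality,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 order = as.integer(order), causal = isTRUE(causal)),
            class = "filter_spec")
}

# RBJ-cookbook biquad notch; returns list(b, a) normalised to a[1] = 1.
design_notch <- function(mains_hz, fs, q) {
  if (mains_hz >= fs / 2) {
    stop("notch frequency must be below the Nyquist frequency", call. = FALSE)
  }
  w0 <- 2 * pi * mains_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

design_bandpass <- function(low_hz, high_hz, fs, order) {
  if (high_hz >= fs / 2) {
    stop("band-pass upper edge must be below the Nyquist frequency",
         call. = FALSE)
  }
  bt <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  list(b = as.numeric(bt$b), a = as.numeric(bt$a))
}

#' Create a stateful filter bank
#'
#' Builds the notch + band-pass chain for a given sampling rate with one
#' filter state per channel per stage. Passing the returned bank through
#' [filter_bank_apply()] chunk by chunk yields output identical to filtering
#' the whole signal at once, which is the contract the online decoder relies
#' on.
#'
#' @param spec a [filter_spec()].
#' @param sampling_rate_hz sampling rate in Hz.
#' @param n_channels number of channels (default 6).
#' @param stages which stages to include: subset of `c("notch", "bandpass")`.
#' @return an object of class `femg_filter_bank`.
#' @export
filter_bank <- function(spec, sampling_rate_hz, n_channels = 6L,
                        stages = c("notch", "bandpass")) {
  stages <- match.arg(stages, several.ok = TRUE)
  filts <- list()
  if ("notch" %in% stages) {
    filts$notch <- design_notch(spec$mains_hz, sampling_rate_hz,
                                spec$notch_quality)
  }
  if ("bandpass" %in% stages) {
    filts$bandpass <- design_bandpass(spec$band_low_hz, spec$band_high_hz,
                                      sampling_rate_hz, spec$order)
  }
  state <- lapply(filts, function(f) {
    nz <- max(length(f$b), length(f$a)) - 1L
    matrix(0, nrow = nz, ncol = n_channels)
  })
  structure(list(filters = filts, state = state, n_channels = n_channels,
                 sampling_rate_hz = sampling_rate_hz),
            class = "femg_filter_bank")
}

#' Apply a filter bank to a chunk of samples
#'
#' @param bank a [filter_bank()].
#' @param samples numeric matrix (time x channels).
#' @return list with `samples` (filtered chunk) and `bank` (updated state).
#' @export
filter_bank_apply <- function(bank, samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) != bank$n_channels) stop("wrong channel count")
  out <- samples
  for (stage in names(bank$filters)) {
    f <- bank$filters[[stage]]
    for (ch in seq_len(ncol(out))) {
      r <- iir_df2t(f$b, f$a, out[, ch], bank$state[[stage]][, ch])
      out[, ch] <- r$y
      bank$state[[stage]][, ch] <- r$zf
    }
  }
  list(samples = out, bank = bank)
}

apply_stage <- function(recording, spec, stages) {
  if (spec$causal) {
    bank <- filter_bank(spec, recording$sampling_rate_hz,
                        ncol(recording$samples), stages)
    recording$samples <- filter_bank_apply(bank, recording$samples)$samples
  } else {
    # zero-phase (offline only): forward-backward per stage per channel
    bank <- filter_bank(spec, recording$sampling_rate_hz,
                        ncol(recording$samples), stages)
    for (stage in names(bank$filters)) {
      f <- bank$filters[[stage]]
      for (ch in seq_len(ncol(recording$samples))) {
        recording$samples[, ch] <- as.numeric(
          signal::filtfilt(f$b, f$a, recording$samples[, ch]))
      }
    }
  }
  recording
}

#' Notch-filter a recording
#'
#' IIR notch at the mains frequency, applied per channel. Events and
#' metadata are untouched.
#'
#' @param recording a [femg_recording()].
#' @param spec a [filter_spec()].
#' @return the filtered recording.
#' @export
notch_filter <- function(recording, spec = filter_spec()) {
  apply_stage(recording, spec, "notch")
}

#' Band-pass filter a recording
#'
#' Second-order Butterworth band-pass (default 10-450 Hz) per channel.
#'
#' @inheritParams notch_filter
#' @return the filtered recording.
#' @export
bandpass_filter <- function(recording, spec = filter_spec()) {
  apply_stage(recording, spec, "bandpass")
}

#' Preprocess a recording (notch then band-pass)
#'
#' The full filtering chain used for both offline analysis and the online
#' stream: notch at the mains frequency followed by the 10-450 Hz
#' second-order Butterworth band-pass, causal by default.
#'
#' @inheritParams notch_filter
#' @return the preprocessed recording.
#' @export
preprocess_recording <- function(recording, spec = filter_spec()) {
  apply_stage(recording, spec, c("notch", "bandpass"))
}
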