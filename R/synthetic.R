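# Seeded synthetic fEMG: amplitude-modulated band-limited Gaussian noise per
# movement epoch, scaled across channels by a cross-talk gain profile, plus a
# mains sinusoid and baseline instrumentation noise.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Cross-talk profile of the six facial movements
#'
#' The gain matrix maps each movement to the amplitude it induces on each of
#' the six electrodes (rows: the six movements plus REST; columns: channels
#' 1-6). Each movement has a strict maximum on its main channel (LEb on 1,
#' LEBO on 2, REBO on 3, Bk on 4, TML on 5, TMR on 6) and the REST row is
#' zero. The default encodes the qualitative structure seen on real
#' recordings: the jaw clench (Bk) bleeds into every channel and has the
#' largest amplitude; lifting the eyebrows (LEb) is confined to the forehead
#' electrode; the slow blinks (LEBO/REBO) are the weakest; amplitude ordering
#' Bk > LEb > TML = TMR > LEBO = REBO.
#'
#' @param gains 7 x 6 numeric matrix (rows named by [all_labels()]); finite,
#'   non-negative, REST row zero, strict main-channel maxima.
#' @param burst_band_hz length-2 band (Hz) of the movement bursts.
#' @param mains_hz mains interference frequency (50 Hz default).
#' @param mains_amplitude mains sinusoid amplitude (signal units).
#' @param baseline_noise_sd standard deviation of the always-on baseline
#'   noise (signal units).
#' @return an object of class `crosstalk_profile`.
#' @export
crosstalk_profile <- function(gains, burst_band_hz = c(20, 450),
                              mains_hz = 50, mains_amplitude = 0.01,
                              baseline_noise_sd = 0.02) {
  gains <- as.matrix(gains)
  stopifnot(nrow(gains) == 7L, ncol(gains) == 6L,
            all(is.finite(gains)), all(gains >= 0))
  rownames(gains) <- all_labels()
  if (any(gains["REST", ] != 0)) stop("REST row must be zero", call. = FALSE)
  mc <- main_channel()
  for (m in movement_labels()) {
    g <- gains[m, ]
    if (!(g[mc[[m]]] > max(g[-mc[[m]]]))) {
      stop("main channel gain must be the strict maximum for ", m,
           call. = FALSE)
    }
  }
  stopifnot(length(burst_band_hz) == 2L, burst_band_hz[1] < burst_band_hz[2],
            mains_hz > 0, mains_amplitude >= 0, baseline_noise_sd >= 0)
  structure(list(gains = gains, burst_band_hz = burst_band_hz,
                 mains_hz = mains_hz, mains_amplitude = mains_amplitude,
                 baseline_noise_sd = baseline_noise_sd),
            class = "crosstalk_profile")
}

#' @rdname crosstalk_profile
#' @export
default_crosstalk_profile <- function() {
  g <- matrix(0, nrow = 7, ncol = 6,
              dimnames = list(all_labels(), channel_labels()))
  g["LEb",  1] <- 0.60                       # forehead only
  g["LEBO", 2] <- 0.15
  g["REBO", 3] <- 0.15; g["REBO", 1] <- 0.04 # blink bleeds to forehead
  g["Bk", ]    <- c(0.25, 0.20, 0.20, 1.00, 0.10, 0.10) # clench hits all
  g["TML", 5]  <- 0.40; g["TML", 2] <- 0.08; g["TML", 4] <- 0.10
  g["TMR", 6]  <- 0.40; g["TMR", 3] <- 0.08
  crosstalk_profile(g)
}

#' Acquisition protocol configuration
#'
#' One round presents the six movements once each in random order; every
#' action lasts `action_duration_s` (about 3 s) preceded by a
#' `rest_between_s` (5 s) rest, with the prompt at action onset.
#'
#' @param n_rounds number of rounds (default 20).
#' @param action_duration_s action length in seconds (default 3).
#' @param rest_between_s rest before each action in seconds (default 5).
#' @param sampling_rate_hz sampling rate in Hz (default 1000; must be at
#'   least 900 to support the 450 Hz band edge).
#' @param seed integer seed for reproducible generation.
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(n_rounds = 20L, action_duration_s = 3,
                            rest_between_s = 5, sampling_rate_hz = 1000,
                            seed = 1L) {
  if (action_duration_s <= 0 || rest_between_s <= 0) {
    stop("durations must be positive", call. = FALSE)
  }
  if (sampling_rate_hz < 900) {
    stop("sampling rate must be >= 900 Hz to carry the 450 Hz band edge",
         call. = FALSE)
  }
  structure(list(n_rounds = as.integer(n_rounds),
                 action_duration_s = action_duration_s,
                 rest_between_s = rest_between_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

# unit-RMS band-limited Gaussian noise, n samples
burst_noise <- function(n, band_hz, fs) {
  bt <- signal::butter(4, pmin(band_hz / (fs / 2), 0.99), type = "pass")
  x <- iir_df2t(as.numeric(bt$b), as.numeric(bt$a), stats::rnorm(n),
                rep(0, max(length(bt$b), length(bt$a)) - 1))$y
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# raised-cosine on/off envelope, ramp_ms at each end
burst_envelope <- function(n, fs, ramp_ms = 100) {
  nr <- min(round(ramp_ms / 1000 * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    env[seq_len(nr)] <- ramp
    env[n - nr + seq_len(nr)] <- rev(ramp)
  }
  env
}

# background: baseline noise + common-phase mains sinusoid
background_samples <- function(n, fs, profile) {
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  mains <- profile$mains_amplitude * sin(2 * pi * profile$mains_hz * t + phase)
  matrix(stats::rnorm(n * 6, sd = profile$baseline_noise_sd), ncol = 6) + mains
}

# add one movement burst into samples[rows, ] (in place value semantics)
add_burst <- function(samples, rows, label, profile, fs) {
  gains <- profile$gains[label, ]
  env <- burst_envelope(length(rows), fs)
  for (ch in which(gains > 0)) {
    samples[rows, ch] <- samples[rows, ch] +
      gains[ch] * env * burst_noise(length(rows), profile$burst_band_hz, fs)
  }
  samples
}

#' Generate one acquisition round
#'
#' The six movements appear once each in seeded random order; each action of
#' `action_duration_s` seconds follows a `rest_between_s` rest, with the
#' prompt event at action onset. Identical `(profile, config, round_seed)`
#' give bit-identical recordings.
#'
#' @param profile a [crosstalk_profile()].
#' @param config a [protocol_config()].
#' @param round_seed integer seed for this round.
#' @return a [femg_recording()] with 6 prompt events.
#' @export
generate_round <- function(profile = default_crosstalk_profile(),
                           config = protocol_config(),
                           round_seed = config$seed) {
  fs <- config$sampling_rate_hz
  slot_s <- config$rest_between_s + config$action_duration_s
  n <- round(6 * slot_s * fs)
  with_seed(round_seed, {
    order <- sample(movement_labels())
    samples <- background_samples(n, fs, profile)
    prompt_s <- config$rest_between_s + (0:5) * slot_s
    n_act <- round(config$action_duration_s * fs)
    for (k in 1:6) {
      start <- round(prompt_s[k] * fs) + 1L
      samples <- add_burst(samples, start:(start + n_act - 1L), order[k],
                           profile, fs)
    }
    femg_recording(samples, fs,
                   events = data.frame(prompt_time_s = prompt_s,
                                       label = order,
                                       stringsAsFactors = FALSE))
  })
}

#' Generate a full offline dataset
#'
#' `config$n_rounds` independent rounds (default 20) with distinct seeds
#' derived from `config$seed`.
#'
#' @inheritParams generate_round
#' @return list of [femg_recording()], one per round.
#' @export
generate_dataset <- function(profile = default_crosstalk_profile(),
                             config = protocol_config()) {
  stopifnot(config$n_rounds >= 1)
  lapply(seq_len(config$n_rounds), function(i) {
    generate_round(profile, config,
                   round_seed = (config$seed + 104729 * i) %% 2147483647)
  })
}

#' Generate a continuous online stream with ground truth
#'
#' Realises an intended label sequence (REST segments allowed) as one
#' continuous signal, keeping the per-sample ground-truth label for decoder
#' scoring. Non-REST segments get a prompt event at onset.
#'
#' @param profile a [crosstalk_profile()].
#' @param intended_sequence data.frame with columns `label` and
#'   `duration_s` (> 0).
#' @param config a [protocol_config()] (sampling rate and seed are used).
#' @return a [femg_recording()] with a `truth` label per sample.
#' @export
generate_online_stream <- function(profile, intended_sequence,
                                   config = protocol_config()) {
  seqd <- as.data.frame(intended_sequence)
  if (nrow(seqd) == 0L) stop("intended sequence must be non-empty",
                             call. = FALSE)
  stopifnot(all(c("label", "duration_s") %in% names(seqd)),
            all(seqd$duration_s > 0))
  for (l in seqd$label) assert_label(l)
  fs <- config$sampling_rate_hz
  n_seg <- round(seqd$duration_s * fs)
  n <- sum(n_seg)
  with_seed(config$seed, {
    samples <- background_samples(n, fs, profile)
    truth <- rep("REST", n)
    offsets <- cumsum(c(0L, n_seg[-length(n_seg)]))
    ev_t <- numeric(0); ev_l <- character(0)
    for (k in seq_len(nrow(seqd))) {
      lab <- seqd$label[k]
      rows <- offsets[k] + seq_len(n_seg[k])
      truth[rows] <- lab
      if (lab != "REST") {
        samples <- add_burst(samples, rows, lab, profile, fs)
        ev_t <- c(ev_t, offsets[k] / fs); ev_l <- c(ev_l, lab)
      }
    }
    femg_recording(samples, fs,
                   events = data.frame(prompt_time_s = ev_t, label = ev_l,
                                       stringsAsFactors = FALSE),
                   truth = truth)
  })
}
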