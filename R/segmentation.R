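#' Sliding-window specification
#'
#' Windows are 200 ms long and slide by 50 ms. For every prompt, the active
#' span runs from 1,500 to 2,650 ms after the prompt (20 windows carrying the
#' prompt's movement label) and the 350 ms immediately before the prompt
#' yields 4 REST windows. Window start offsets are half-open
#' `[start, start + window)`, so the last active window starts at
#' prompt + 2,450 ms and ends exactly at 2,650 ms.
#'
#' @param window_ms window length (default 200).
#' @param step_ms sliding step (default 50).
#' @param active_start_ms start of the labelled span after the prompt
#'   (default 1500).
#' @param active_end_ms end of the labelled span after the prompt
#'   (default 2650).
#' @param rest_pre_ms length of the pre-prompt REST span (default 350).
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(window_ms = 200, step_ms = 50,
                        active_start_ms = 1500, active_end_ms = 2650,
                        rest_pre_ms = 350) {
  stopifnot(window_ms > 0, step_ms > 0, active_end_ms > active_start_ms,
            window_ms <= active_end_ms - active_start_ms,
            window_ms <= rest_pre_ms)
  structure(list(window_ms = window_ms, step_ms = step_ms,
                 active_start_ms = active_start_ms,
                 active_end_ms = active_end_ms,
                 rest_pre_ms = rest_pre_ms),
            class = "window_spec")
}

#' Number of sliding windows in a span
#'
#' `floor((span - window) / step) + 1`. The 1,150 ms active span holds 20
#' windows of 200 ms at a 50 ms step; the 350 ms rest span holds 4.
#'
#' @param span_ms span length in ms.
#' @param window_ms window length in ms.
#' @param step_ms step in ms.
#' @return integer window count.
#' @export
count_windows <- function(span_ms, window_ms = 200, step_ms = 50) {
  stopifnot(step_ms > 0, window_ms > 0)
  if (span_ms < window_ms) {
    stop("span shorter than the window", call. = FALSE)
  }
  as.integer(floor((span_ms - window_ms) / step_ms) + 1)
}

#' Segment a recording into labelled windows
#'
#' Per prompt: `count_windows(active span)` windows labelled with the
#' prompt's movement, plus `count_windows(rest span)` REST windows from just
#' before the prompt. Prompts whose spans fall outside the recording are
#' skipped with a warning. Ordering is stable: by prompt, REST windows first,
#' then active windows by start time.
#'
#' @param recording a (preprocessed) [femg_recording()] with events.
#' @param spec a [window_spec()].
#' @param round_index integer tag carried into each window (provenance).
#' @return list of labelled windows; each has `samples` (window x 6 matrix),
#'   `label`, `round_index`, `prompt_index`.
#' @export
segment_recording <- function(recording, spec = window_spec(),
                              round_index = 1L) {
  fs <- recording$sampling_rate_hz
  n <- nrow(recording$samples)
  wlen <- round(spec$window_ms / 1000 * fs)
  step <- round(spec$step_ms / 1000 * fs)
  out <- list()
  ev <- recording$events
  for (p in seq_len(nrow(ev))) {
    p0 <- round(ev$prompt_time_s[p] * fs)  # sample index of the prompt (0-based)
    rest_first <- p0 - round(spec$rest_pre_ms / 1000 * fs)
    act_first <- p0 + round(spec$active_start_ms / 1000 * fs)
    act_last_end <- p0 + round(spec$active_end_ms / 1000 * fs)
    if (rest_first < 0 || act_last_end > n) {
      warning(sprintf("prompt %d at %.3f s too close to the recording edge; skipped",
                      p, ev$prompt_time_s[p]))
      next
    }
    n_rest <- count_windows(spec$rest_pre_ms, spec$window_ms, spec$step_ms)
    n_act <- count_windows(spec$active_end_ms - spec$active_start_ms,
                           spec$window_ms, spec$step_ms)
    starts <- c(rest_first + (seq_len(n_rest) - 1L) * step,
                act_first + (seq_len(n_act) - 1L) * step)
    labels <- c(rep("REST", n_rest), rep(ev$label[p], n_act))
    for (w in seq_along(starts)) {
      out[[length(out) + 1L]] <- list(
        samples = recording$samples[starts[w] + seq_len(wlen), , drop = FALSE],
        label = labels[w], round_index = round_index, prompt_index = p)
    }
  }
  out
}

#' Segment a whole dataset
#'
#' @param recordings list of [femg_recording()] (one per round).
#' @param spec a [window_spec()].
#' @return flat list of labelled windows with `round_index` set per round.
#' @export
segment_dataset <- function(recordings, spec = window_spec()) {
  unlist(lapply(seq_along(recordings), function(i) {
    segment_recording(recordings[[i]], spec, round_index = i)
  }), recursive = FALSE)
}
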