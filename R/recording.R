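#' Construct a multi-channel fEMG recording
#'
#' A `femg_recording` bundles a numeric sample matrix (time x 6 channels),
#' the sampling rate, channel labels and an event table of movement prompts.
#' Optionally a per-sample ground-truth label vector is attached (used by
#' synthetic online streams for decoder scoring).
#'
#' @param samples numeric matrix, one row per sample, 6 columns.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param channel_labels character vector of 6 channel names.
#' @param events data.frame with columns `prompt_time_s` (numeric, strictly
#'   increasing, within the signal extent) and `label` (movement labels).
#' @param truth optional character vector of per-sample ground-truth labels
#'   (length `nrow(samples)`).
#' @return an object of class `femg_recording`.
#' @export
femg_recording <- function(samples, sampling_rate_hz,
                           channel_labels = femgfci::channel_labels(),
                           events = empty_events(), truth = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 6L) {
    stop("a recording must have exactly 6 channels, got ", ncol(samples),
         call. = FALSE)
  }
  storage.mode(samples) <- "double"
  if (length(channel_labels) != 6L) stop("need 6 channel labels", call. = FALSE)
  stopifnot(is.numeric(sampling_rate_hz), sampling_rate_hz > 0)
  events <- as.data.frame(events)
  if (!all(c("prompt_time_s", "label") %in% names(events))) {
    stop("events must have columns prompt_time_s and label", call. = FALSE)
  }
  if (nrow(events) > 1L && any(diff(events$prompt_time_s) <= 0)) {
    stop("event times must be strictly increasing", call. = FALSE)
  }
  dur <- nrow(samples) / sampling_rate_hz
  if (nrow(events) > 0L &&
      (any(events$prompt_time_s < 0) || any(events$prompt_time_s > dur))) {
    stop("event times must lie within the signal extent", call. = FALSE)
  }
  bad <- setdiff(unique(events$label), all_labels())
  if (length(bad)) stop("unknown event labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(truth) && length(truth) != nrow(samples)) {
    stop("truth must have one label per sample", call. = FALSE)
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate_hz = sampling_rate_hz,
         channel_labels = channel_labels, events = events, truth = truth),
    class = "femg_recording"
  )
}

empty_events <- function() {
  data.frame(prompt_time_s = numeric(0), label = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.femg_recording <- function(x, ...) {
  cat(sprintf("<femg_recording> %d samples x 6 channels @ %g Hz (%.2f s), %d events\n",
              nrow(x$samples), x$sampling_rate_hz,
              nrow(x$samples) / x$sampling_rate_hz, nrow(x$events)))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording a [femg_recording()].
#' @return numeric scalar.
#' @export
recording_duration <- function(recording) {
  nrow(recording$samples) / recording$sampling_rate_hz
}
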