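# Recording I/O. CSV dialect: a header row of channel labels, one sample per
# row, with a sidecar `<name>.events.csv` (columns prompt_time_s,label).
# YAML carries the generator/protocol configuration.

events_path <- function(path) sub("\\.csv$", "", path) |>
  paste0(".events.csv")

#' Write a recording to CSV (+ events sidecar)
#'
#' @param recording a [femg_recording()].
#' @param path output `.csv` path; events go to `<name>.events.csv`.
#' @param meta optional named list written as `# key: value` comment lines
#'   (e.g. seed and config digest) before the header.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(recording, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, as.character, character(1))), con)
  }
  writeLines(sprintf("# sampling_rate_hz: %g", recording$sampling_rate_hz),
             con)
  utils::write.table(as.data.frame(recording$samples), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(recording$events, events_path(path), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a recording
#'
#' @param path input path.
#' @param format `"csv"` (default; `<name>.events.csv` sidecar expected) or
#'   `"edf"`.
#' @param sampling_rate_hz fallback rate if the CSV carries no
#'   `# sampling_rate_hz:` comment.
#' @return a [femg_recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf"),
                           sampling_rate_hz = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  if (format == "edf") return(read_recording_edf(path))
  head_lines <- readLines(path, n = 20)
  meta <- grep("^# sampling_rate_hz:", head_lines, value = TRUE)
  fs <- if (length(meta)) as.numeric(sub(".*:", "", meta[1])) else
    sampling_rate_hz
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (ncol(df) != 6L) {
    stop("wrong channel count: expected 6 columns, got ", ncol(df),
         call. = FALSE)
  }
  ep <- events_path(path)
  if (!file.exists(ep)) stop("missing events sidecar: ", ep, call. = FALSE)
  events <- utils::read.csv(ep, stringsAsFactors = FALSE)
  femg_recording(as.matrix(df), fs, channel_labels = names(df),
                 events = events)
}

#' Write / read generator configuration as YAML
#'
#' Serialises a [protocol_config()] together with a [crosstalk_profile()]
#' (gain matrix flattened with row names preserved).
#'
#' @param config a [protocol_config()].
#' @param profile a [crosstalk_profile()].
#' @param path YAML file path.
#' @return `path` invisibly; `read_fci_config()` returns
#'   `list(config, profile)`.
#' @export
write_fci_config <- function(config, profile, path) {
  obj <- list(
    protocol = unclass(config),
    profile = list(gains = stats::setNames(
      lapply(seq_len(nrow(profile$gains)),
             function(i) as.numeric(profile$gains[i, ])),
      rownames(profile$gains)),
      burst_band_hz = profile$burst_band_hz,
      mains_hz = profile$mains_hz,
      mains_amplitude = profile$mains_amplitude,
      baseline_noise_sd = profile$baseline_noise_sd))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_fci_config
#' @export
read_fci_config <- function(path) {
  obj <- yaml::read_yaml(path)
  g <- do.call(rbind, obj$profile$gains[all_labels()])
  list(config = do.call(protocol_config, obj$protocol[
    c("n_rounds", "action_duration_s", "rest_between_s",
      "sampling_rate_hz", "seed")]),
    profile = crosstalk_profile(
      g, burst_band_hz = as.numeric(obj$profile$burst_band_hz),
      mains_hz = obj$profile$mains_hz,
      mains_amplitude = obj$profile$mains_amplitude,
      baseline_noise_sd = obj$profile$baseline_noise_sd))
}

#' Write a feature matrix as CSV
#'
#' One row per window, feature columns plus a final `label` column.
#'
#' @param fm a [assemble_features()] matrix.
#' @param path output path.
#' @param meta optional named list of `# key: value` comments.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(fm, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, as.character, character(1))), con)
  }
  writeLines(sprintf("# mode: %s", fm$mode), con)
  df <- data.frame(fm$x, check.names = FALSE)
  df$label <- fm$labels
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  head_lines <- readLines(path, n = 20)
  meta <- grep("^# mode:", head_lines, value = TRUE)
  mode <- if (length(meta)) trimws(sub("^# mode:", "", meta[1])) else "AF"
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  structure(list(x = as.matrix(df[, setdiff(names(df), "label"),
                                  drop = FALSE]),
                 labels = df$label, mode = mode),
            class = "feature_matrix")
}
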