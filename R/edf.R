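# Minimal EDF+ I/O: 16-bit signals in 1 s data records plus one
# "EDF Annotations" channel carrying the prompt events as time-stamped
# annotation lists (TALs). Written by hand because no EDF package is
# available to this package; covers exactly the subset it writes (EDF+C,
# equal-length records, final record zero-padded).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width)  # left-justified, space padded
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE), width)

# shortest representation of a float that fits the 8-char EDF field
num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(signif(x, d), format = "g", digits = d, width = 0)
    if (nchar(s) <= 8) return(pad_field(s, 8))
  }
  pad_field("0", 8)
}

#' Write a recording as EDF+ with annotations
#'
#' Signals are scaled to the 16-bit digital range per channel; events become
#' EDF+ annotations. The signal is zero-padded to a whole number of 1 s
#' records.
#'
#' @param recording a [femg_recording()].
#' @param path output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(recording, path) {
  fs <- recording$sampling_rate_hz
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  x <- recording$samples
  n_rec <- ceiling(nrow(x) / fs)
  if (nrow(x) < n_rec * fs) {
    x <- rbind(x, matrix(0, n_rec * fs - nrow(x), ncol(x)))
  }
  ns <- ncol(x) + 1L  # + annotation channel
  ann_len <- 60L      # 16-bit samples per record reserved for annotations

  phys_min <- apply(x, 2, min); phys_max <- apply(x, 2, max)
  same <- phys_max - phys_min < 1e-12
  phys_max[same] <- phys_min[same] + 1
  # quantise against the bounds exactly as the 8-char header will carry them
  phys_min <- vapply(phys_min, function(v) as.numeric(trimws(num8(v))),
                     numeric(1))
  phys_max <- vapply(phys_max, function(v) as.numeric(trimws(num8(v))),
                     numeric(1))
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L * (1L + ns)
  wr(pad_field("0", 8)); wr(pad_field("synthetic fEMG", 80))
  wr(pad_field("femgfci export", 80))
  wr(pad_field("01.01.26", 8)); wr(pad_field("00.00.00", 8))
  wr(num_field(header_bytes, 8)); wr(pad_field("EDF+C", 44))
  wr(num_field(n_rec, 8)); wr(num_field(1, 8)); wr(num_field(ns, 4))

  labels <- c(substr(recording$channel_labels, 1, 16), "EDF Annotations")
  for (l in labels) wr(pad_field(l, 16))
  for (i in 1:ns) wr(pad_field("", 80))                  # transducer
  for (i in 1:ns) wr(pad_field(if (i <= ns - 1) "uV" else "", 8))
  for (i in 1:ns) wr(if (i <= ns - 1) num8(phys_min[i]) else num_field(-1, 8))
  for (i in 1:ns) wr(if (i <= ns - 1) num8(phys_max[i]) else num_field(1, 8))
  for (i in 1:ns) wr(num_field(dig_min, 8))
  for (i in 1:ns) wr(num_field(dig_max, 8))
  for (i in 1:ns) wr(pad_field("", 80))                  # prefiltering
  for (i in 1:ns) wr(num_field(if (i <= ns - 1) fs else ann_len, 8))
  for (i in 1:ns) wr(pad_field("", 32))

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  ev <- recording$events
  for (r in seq_len(n_rec)) {
    rows <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(ncol(x))) {
      dig <- round((x[rows, ch] - phys_min[ch]) / scale[ch] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2, endian = "little")
    }
    # annotation TALs: record time-keeping TAL, then events in this record;
    # every TAL is NUL-terminated (NULs handled at the raw level)
    in_rec <- which(ev$prompt_time_s >= r - 1 & ev$prompt_time_s < r)
    tals <- c(sprintf("+%d\x14\x14", r - 1L),
              sprintf("+%.3f\x14%s\x14", ev$prompt_time_s[in_rec],
                      ev$label[in_rec]))
    raw_tal <- unlist(lapply(tals, function(s) c(charToRaw(s), as.raw(0))))
    if (length(raw_tal) > 2L * ann_len) {
      stop("too many events in one record for the annotation channel",
           call. = FALSE)
    }
    writeBin(c(raw_tal, raw(2L * ann_len - length(raw_tal))), con)
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into a recording
#'
#' Supports 16-bit EDF with equal-length records; an `EDF Annotations`
#' channel, if present, is parsed into prompt events.
#'
#' @param path `.edf` file path.
#' @return a [femg_recording()].
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                     # header bytes
  rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(1:ns, function(i) rd(16), character(1)))
  for (i in 1:ns) rd(80)
  for (i in 1:ns) rd(8)                     # phys dim
  phys_min <- as.numeric(vapply(1:ns, function(i) rd(8), character(1)))
  phys_max <- as.numeric(vapply(1:ns, function(i) rd(8), character(1)))
  dig_min <- as.numeric(vapply(1:ns, function(i) rd(8), character(1)))
  dig_max <- as.numeric(vapply(1:ns, function(i) rd(8), character(1)))
  for (i in 1:ns) rd(80)
  spr <- as.integer(vapply(1:ns, function(i) rd(8), character(1)))
  for (i in 1:ns) rd(32)

  is_ann <- labels == "EDF Annotations"
  sig_idx <- which(!is_ann)
  if (length(sig_idx) != 6L) {
    stop("wrong channel count: expected 6 signals, got ", length(sig_idx),
         call. = FALSE)
  }
  chunks <- lapply(sig_idx, function(i) vector("list", n_rec))
  ann_text <- character(0)
  for (r in seq_len(n_rec)) {
    for (i in 1:ns) {
      if (is_ann[i]) {
        raw <- readBin(con, "raw", n = 2L * spr[i])
        ann_text <- c(ann_text, rawToChar(raw[raw != as.raw(0)]))
      } else {
        dig <- readBin(con, "integer", n = spr[i], size = 2,
                       endian = "little")
        j <- match(i, sig_idx)
        chunks[[j]][[r]] <- phys_min[i] +
          (dig - dig_min[i]) * (phys_max[i] - phys_min[i]) /
            (dig_max[i] - dig_min[i])
      }
    }
  }
  samples <- do.call(cbind, lapply(chunks, function(ch) unlist(ch)))
  fs <- spr[sig_idx[1]] / rec_dur

  events <- empty_events()
  if (length(ann_text)) {
    tals <- unlist(strsplit(paste(ann_text, collapse = ""), "\x14\\+"))
    for (tal in tals[-1]) {
      parts <- strsplit(tal, "\x14")[[1]]
      if (length(parts) >= 2L && nzchar(parts[2])) {
        events <- rbind(events,
                        data.frame(prompt_time_s = as.numeric(parts[1]),
                                   label = parts[2],
                                   stringsAsFactors = FALSE))
      }
    }
    if (nrow(events)) events <- events[order(events$prompt_time_s), ]
  }
  femg_recording(samples, fs,
                 channel_labels = labels[sig_idx], events = events)
}
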