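#' Movement label vocabulary
#'
#' The six facial movements used for intent recognition, plus REST. The six
#' are: lift eyebrows (LEb), left eye blink once slowly (LEBO), right eye
#' blink once slowly (REBO), bick/clench (Bk), tilt mouth left (TML) and tilt
#' mouth right (TMR). Each movement has one "main" recording channel
#' (forehead, left/right eye corner, masseter, left/right mouth corner).
#'
#' @return `movement_labels()` returns the six action labels;
#'   `all_labels()` additionally includes `"REST"` (last).
#' @export
movement_labels <- function() {
  c("LEb", "LEBO", "REBO", "Bk", "TML", "TMR")
}

#' @rdname movement_labels
#' @export
all_labels <- function() {
  c(movement_labels(), "REST")
}

#' @rdname movement_labels
#' @export
channel_labels <- function() {
  c("forehead", "left_eye", "right_eye", "masseter", "mouth_left", "mouth_right")
}

#' Main recording channel of each movement
#'
#' Electrode-to-movement pairing: channel 1 carries LEb, 2 LEBO, 3 REBO,
#' 4 Bk, 5 TML, 6 TMR.
#'
#' @return named integer vector, names are the six movement labels.
#' @export
main_channel <- function() {
  stats::setNames(1:6, movement_labels())
}

assert_label <- function(label) {
  if (length(label) != 1L || !label %in% all_labels()) {
    stop("unknown movement label: ", paste(label, collapse = ","), call. = FALSE)
  }
  label
}
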