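# Two-stage finite-state intent decoder. Stage one: a debounced selector
# movement picks an axis or the gripper (REBO->X, LEBO->Y, TMR->Z,
# TML->gripper) and announces the choice. Stage two: LEb picks the positive
# direction, Bk the negative; axis motion is hold-to-move, the gripper is a
# guarded momentary command with self-locking state. A second action is only
# valid within 5 s of the first recognition (or while it itself persists).

#' The eight decoder commands
#' @return character vector: signed axis moves plus gripper open/close.
#' @export
command_set <- function() {
  c("+X", "-X", "+Y", "-Y", "+Z", "-Z", "close_gripper", "open_gripper")
}

#' The twelve broadcast strings
#'
#' Audio-feedback texts: one per first movement (axis/gripper selection) and
#' one per second movement (direction or gripper action).
#' @return character vector of 12 strings.
#' @export
broadcast_strings <- function() {
  c("Left or right", "Forward or back", "Up or down", "Gripper",
    "Left", "Right", "Back", "Forward", "Up", "Down", "Close", "Open")
}

selector_table <- function() {
  data.frame(label = c("REBO", "LEBO", "TMR", "TML"),
             selector = c("X", "Y", "Z", "Gripper"),
             broadcast = c("Left or right", "Forward or back", "Up or down",
                           "Gripper"),
             stringsAsFactors = FALSE)
}

# second-action mapping; LEb is the positive direction, Bk the negative;
# +X is announced "Left", +Y "Back", +Z "Up" (the operator faces +Y)
second_table <- function(gripper_swap = FALSE) {
  d <- data.frame(
    selector = rep(c("X", "Y", "Z", "Gripper"), each = 2),
    label = rep(c("LEb", "Bk"), 4),
    command = c("+X", "-X", "+Y", "-Y", "+Z", "-Z",
                "close_gripper", "open_gripper"),
    broadcast = c("Left", "Right", "Back", "Forward", "Up", "Down",
                  "Close", "Open"),
    stringsAsFactors = FALSE)
  if (gripper_swap) {  # follow the alternative text convention (Bk closes)
    d$command[7:8] <- c("open_gripper", "close_gripper")
    d$broadcast[7:8] <- c("Open", "Close")
  }
  d
}

#' Decoder configuration
#'
#' @param second_action_timeout_s validity window of the second action after
#'   the first is recognised (default 5 s).
#' @param debounce_windows consecutive identical non-REST window predictions
#'   required to accept a selector (default 5, i.e. 250 ms at the 50 ms
#'   window step).
#' @param second_debounce_windows consecutive identical LEb/Bk predictions
#'   required to accept the second action (default 3, i.e. 150 ms);
#'   transition windows at burst onset are easily misread, so acting on a
#'   single window would start motion in the wrong direction.
#' @param window_step_ms prediction cadence in ms (default 50).
#' @param gripper_z_limit_cm gripper commands are only honoured below this
#'   height over the desktop (default 10 cm).
#' @param rest_hysteresis_windows consecutive non-matching windows required
#'   to stop a held axis motion, so single-window misclassifications do not
#'   stutter the arm (default = `debounce_windows`).
#' @param gripper_swap if `TRUE`, swap the gripper convention so Bk closes
#'   and LEb opens.
#' @param desktop list with `x` and `y` ranges defining the desktop
#'   rectangle used by the gripper guard.
#' @return an object of class `decoder_config`.
#' @export
decoder_config <- function(second_action_timeout_s = 5, debounce_windows = 5L,
                           second_debounce_windows = 3L,
                           window_step_ms = 50, gripper_z_limit_cm = 10,
                           rest_hysteresis_windows = debounce_windows,
                           gripper_swap = FALSE,
                           desktop = list(x = c(20, 120), y = c(-70, 100))) {
  stopifnot(second_action_timeout_s > 0, debounce_windows >= 1,
            second_debounce_windows >= 1,
            window_step_ms > 0, rest_hysteresis_windows >= 1)
  structure(list(second_action_timeout_s = second_action_timeout_s,
                 debounce_windows = as.integer(debounce_windows),
                 second_debounce_windows = as.integer(second_debounce_windows),
                 window_step_ms = window_step_ms,
                 gripper_z_limit_cm = gripper_z_limit_cm,
                 rest_hysteresis_windows = as.integer(rest_hysteresis_windows),
                 gripper_swap = isTRUE(gripper_swap), desktop = desktop),
            class = "decoder_config")
}

#' Fresh decoder state
#'
#' Stage 0 means waiting for a first (selector) action; stage 1 means a
#' selector is pending and the 5 s deadline is running; stage 2 means a held
#' second action is driving axis motion.
#' @return an object of class `decoder_state`.
#' @export
decoder_state <- function() {
  structure(list(stage = 0L, pending = NULL, deadline_s = NA_real_,
                 active_cmd = NULL, active_label = NULL,
                 run_label = "REST", run_count = 0L, break_count = 0L),
            class = "decoder_state")
}

over_desktop <- function(pose, desktop) {
  pose[["x"]] >= desktop$x[1] && pose[["x"]] <= desktop$x[2] &&
    pose[["y"]] >= desktop$y[1] && pose[["y"]] <= desktop$y[2]
}

event_row <- function(t, kind, payload, lifecycle = NA_character_) {
  data.frame(time_s = t, kind = kind, payload = payload,
             lifecycle = lifecycle, stringsAsFactors = FALSE)
}

#' Advance the decoder by one window prediction
#'
#' @param state a [decoder_state()].
#' @param label predicted movement label for this window.
#' @param now_s current time in seconds.
#' @param arm_pose named numeric (`x`, `y`, `z`) end-effector pose in cm,
#'   used by the gripper safety guard.
#' @param config a [decoder_config()].
#' @return list with `state`, and `events` (data.frame: time_s, kind in
#'   command/broadcast/refusal, payload, lifecycle in start/stop/pulse).
#' @export
decoder_step <- function(state, label, now_s, arm_pose,
                         config = decoder_config()) {
  assert_label(label)
  ev <- list()
  emit <- function(kind, payload, lifecycle = NA_character_) {
    ev[[length(ev) + 1L]] <<- event_row(now_s, kind, payload, lifecycle)
  }
  sel <- selector_table()
  sec <- second_table(config$gripper_swap)

  # run-length tracking of consecutive identical predictions
  if (identical(label, state$run_label)) {
    state$run_count <- state$run_count + 1L
  } else {
    state$run_label <- label
    state$run_count <- 1L
  }

  if (state$stage == 2L) {
    # held axis motion: continue while the second label persists
    if (identical(label, state$active_label)) {
      state$break_count <- 0L
      state$deadline_s <- now_s + config$second_action_timeout_s
    } else {
      state$break_count <- state$break_count + 1L
      if (state$break_count >= config$rest_hysteresis_windows) {
        emit("command", state$active_cmd, "stop")
        state$stage <- 0L
        state$pending <- NULL
        state$active_cmd <- NULL
        state$active_label <- NULL
        state$deadline_s <- NA_real_
        state$break_count <- 0L
      }
    }
    return(list(state = state, events = do.call(rbind, c(list(NULL), ev))))
  }

  if (state$stage == 1L && !is.na(state$deadline_s) &&
      now_s > state$deadline_s) {
    # second action not begun in time: back to stage 0, label ignored below
    state$stage <- 0L
    state$pending <- NULL
    state$deadline_s <- NA_real_
    # fall through so this very window may still start a new selection run
  }

  if (state$stage == 0L) {
    hit <- sel$selector[match(label, sel$label)]
    if (!is.na(hit) && state$run_count >= config$debounce_windows) {
      state$stage <- 1L
      state$pending <- hit
      state$deadline_s <- now_s + config$second_action_timeout_s
      emit("broadcast", sel$broadcast[match(label, sel$label)])
    }
    return(list(state = state, events = do.call(rbind, c(list(NULL), ev))))
  }

  # stage 1: selector pending, waiting for a debounced LEb or Bk
  if (label %in% c("LEb", "Bk") &&
      state$run_count >= config$second_debounce_windows) {
    row <- sec[sec$selector == state$pending & sec$label == label, ]
    if (state$pending == "Gripper") {
      ok <- arm_pose[["z"]] < config$gripper_z_limit_cm &&
        over_desktop(arm_pose, config$desktop)
      if (ok) {
        emit("broadcast", row$broadcast)
        emit("command", row$command, "pulse")
      } else {
        emit("refusal", paste0(row$command, ": gripper guard (z=",
                               round(arm_pose[["z"]], 1), " cm)"))
      }
      state$stage <- 0L
      state$pending <- NULL
      state$deadline_s <- NA_real_
    } else {
      emit("broadcast", row$broadcast)
      emit("command", row$command, "start")
      state$stage <- 2L
      state$active_cmd <- row$command
      state$active_label <- label
      state$break_count <- 0L
      state$deadline_s <- now_s + config$second_action_timeout_s
    }
  }
  list(state = state, events = do.call(rbind, c(list(NULL), ev)))
}

#' Decode a timed sequence of window predictions
#'
#' Folds [decoder_step()] over a label sequence at the window-step cadence
#' and returns the full command/broadcast/refusal log.
#'
#' @param labels character vector of window predictions.
#' @param config a [decoder_config()].
#' @param times_s optional time stamps (default: the window-step cadence).
#' @param arm_pose_provider function(t) returning the arm pose; default a
#'   fixed safe pose at (70, 0, 8) cm.
#' @return data.frame event log (time_s, kind, payload, lifecycle).
#' @export
decode_stream <- function(labels, config = decoder_config(),
                          times_s = NULL, arm_pose_provider = NULL) {
  if (is.null(times_s)) {
    times_s <- seq_along(labels) * config$window_step_ms / 1000
  }
  if (is.null(arm_pose_provider)) {
    arm_pose_provider <- function(t) c(x = 70, y = 0, z = 8)
  }
  state <- decoder_state()
  logs <- list()
  for (i in seq_along(labels)) {
    res <- decoder_step(state, labels[i], times_s[i],
                        arm_pose_provider(times_s[i]), config)
    state <- res$state
    if (!is.null(res$events)) logs[[length(logs) + 1L]] <- res$events
  }
  if (length(logs) == 0L) {
    return(data.frame(time_s = numeric(0), kind = character(0),
                      payload = character(0), lifecycle = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, logs)
}
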