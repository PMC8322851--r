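# End-to-end glue: train the online classifier offline, then close the loop
# by synthesising fEMG for planned intents, streaming it through the causal
# filter chain, predicting per window, decoding intents into commands and
# driving the simulated arm. The planner re-plans from the arm's actual
# state after every intent segment, so occasional window misclassifications
# are corrected rather than accumulated.

#' Train the online intent classifier
#'
#' Generates (or takes) an offline dataset, preprocesses it, segments it
#' and fits one registry classifier on the full feature matrix.
#'
#' @param profile a [crosstalk_profile()].
#' @param config a [protocol_config()].
#' @param mode feature mode (default `"EF"`).
#' @param model registry name (default `"GBC"`).
#' @param recordings optional pre-generated list of recordings (skips
#'   generation).
#' @param fspec a [filter_spec()].
#' @param wspec a [window_spec()].
#' @return object of class `fci_model` with a `$predict(windows)` closure.
#' @export
train_online_model <- function(profile = default_crosstalk_profile(),
                               config = protocol_config(),
                               mode = "EF", model = "GBC",
                               recordings = NULL,
                               fspec = filter_spec(),
                               wspec = window_spec()) {
  if (is.null(recordings)) recordings <- generate_dataset(profile, config)
  recs <- lapply(recordings, preprocess_recording, spec = fspec)
  windows <- segment_dataset(recs, wspec)
  fm <- assemble_features(windows, mode)
  y <- droplevels(as_label_factor(fm$labels))
  spec <- model_registry(model)[[model]]
  fitted <- spec$fit(fm$x, y, seed = config$seed)
  structure(list(model_name = model, mode = mode, fitted = fitted,
                 spec = spec, fspec = fspec, wspec = wspec,
                 format_version = 1L),
            class = "fci_model")
}

#' Predict movement labels for a window list
#' @param object an [train_online_model()] model.
#' @param windows list of windows (as from [segment_recording()], labels
#'   ignored) or a `feature_matrix`.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.fci_model <- function(object, windows, ...) {
  fm <- if (inherits(windows, "feature_matrix")) windows else
    assemble_features(windows, object$mode)
  object$spec$predict(object$fitted, fm$x)
}

# cut a signal buffer into 200 ms / 50 ms windows; returns window list and
# the number of consumed samples (leaving the tail for the next chunk)
buffer_windows <- function(buffer, fs, wspec) {
  wlen <- round(wspec$window_ms / 1000 * fs)
  step <- round(wspec$step_ms / 1000 * fs)
  n <- nrow(buffer)
  if (n < wlen) return(list(windows = list(), consumed = 0L))
  starts <- seq(0L, n - wlen, by = step)
  wins <- lapply(starts, function(s) {
    list(samples = buffer[s + seq_len(wlen), , drop = FALSE], label = "?")
  })
  list(windows = wins, consumed = max(starts) + step)
}

# plan the next intent burst from the simulator state; returns NULL when the
# task is complete, else a data.frame(label, duration_s)
plan_next_intents <- function(sim, dec_cfg) {
  sel_for_axis <- c(x = "REBO", y = "LEBO", z = "TMR")
  second_for_sign <- c(`1` = "LEb", `-1` = "Bk")
  ws <- sim$ws
  gp <- grasp_point(sim$scenario)
  mouth <- c(x = mean(ws$mouth_x), y = mean(ws$mouth_y), z = mean(ws$mouth_z))
  # positioning tolerance: coarse enough that the shortest recognisable
  # burst (~0.7 s, bounded below by the ramps and the debounce) cannot
  # oscillate around the target, and still well inside the 5 cm grasp
  # radius and the 10 cm gripper-height guard
  tol <- 2.0
  segment <- function(first, second, hold_s) {
    data.frame(label = c(first, "REST", second, "REST"),
               duration_s = c(1.0, 0.4, hold_s, 0.6),
               stringsAsFactors = FALSE)
  }
  axis_segment <- function(target, order) {
    for (ax in order) {
      d <- target[[ax]] - sim$pos[[ax]]
      if (abs(d) > tol) {
        # motion continues ~one hysteresis period after the action ends
        hold <- max(abs(d) / sim$speed - 0.3, 0.7)
        return(segment(sel_for_axis[[ax]],
                       second_for_sign[[as.character(sign(d))]],
                       min(hold, 6)))
      }
    }
    NULL
  }
  grip_segment <- function(second) segment("TML", second, 1.0)
  if (!sim$holding_cup && !sim$visited_mouth) {
    seg <- axis_segment(gp, c("x", "y", "z"))
    if (!is.null(seg)) return(seg)
    return(grip_segment(if (dec_cfg$gripper_swap) "Bk" else "LEb"))  # close
  }
  if (sim$holding_cup && !sim$visited_mouth) {
    seg <- axis_segment(mouth, c("z", "x", "y"))
    if (!is.null(seg)) return(seg)
    return(data.frame(label = "REST", duration_s = 1.5,
                      stringsAsFactors = FALSE))  # dwell to drink
  }
  if (sim$holding_cup && sim$visited_mouth) {
    seg <- axis_segment(gp, c("y", "x", "z"))
    if (!is.null(seg)) return(seg)
    return(grip_segment(if (dec_cfg$gripper_swap) "LEb" else "Bk"))  # open
  }
  NULL
}

#' Closed-loop drinking task through the full pipeline
#'
#' Plans facial-movement intents from the simulated arm's state, synthesises
#' the corresponding fEMG stream, filters it causally with carried state,
#' predicts a label per 200 ms window every 50 ms, feeds the predictions to
#' the two-stage decoder and applies the resulting commands to the arm, until
#' the three-stage drinking task completes or the timeout elapses.
#'
#' @param model an [train_online_model()] classifier.
#' @param scenario a [make_scenario()].
#' @param profile a [crosstalk_profile()].
#' @param dec_cfg a [decoder_config()].
#' @param timeout_s simulated-time limit (default 600).
#' @param seed integer seed for the synthetic stream.
#' @param workspace a [fci_workspace()].
#' @return list: `completed`, `elapsed_s`, `events` (decoder log),
#'   `n_windows`, final `sim`.
#' @export
run_fci_task <- function(model, scenario,
                         profile = default_crosstalk_profile(),
                         dec_cfg = decoder_config(), timeout_s = 600,
                         seed = 1L, workspace = fci_workspace()) {
  fs <- 1000
  sim <- new_sim(scenario, workspace)
  bank <- filter_bank(model$fspec, fs)
  dstate <- decoder_state()
  buffer <- matrix(numeric(0), ncol = 6)
  logs <- list()
  t_now <- 0
  n_windows <- 0L
  seg_i <- 0L
  dt <- model$wspec$step_ms / 1000
  while (t_now < timeout_s && !sim$completed) {
    intents <- plan_next_intents(sim, dec_cfg)
    if (is.null(intents)) break
    seg_i <- seg_i + 1L
    stream <- generate_online_stream(
      profile, intents,
      protocol_config(sampling_rate_hz = fs,
                      seed = (seed + 7919 * seg_i) %% 2147483647))
    filt <- filter_bank_apply(bank, stream$samples)
    bank <- filt$bank
    buffer <- rbind(buffer, filt$samples)
    bw <- buffer_windows(buffer, fs, model$wspec)
    if (bw$consumed > 0L) {
      buffer <- buffer[-seq_len(bw$consumed), , drop = FALSE]
    }
    if (length(bw$windows) > 0L) {
      labels <- predict(model, bw$windows)
      for (lab in labels) {
        t_now <- t_now + dt
        res <- decoder_step(dstate, lab, t_now, sim$pos, dec_cfg)
        dstate <- res$state
        if (!is.null(res$events)) logs[[length(logs) + 1L]] <- res$events
        # pulses act immediately; held motion advances the arm this tick
        cmd <- NULL
        if (!is.null(res$events)) {
          pulses <- res$events[res$events$kind == "command" &
                                 res$events$lifecycle == "pulse", ]
          if (nrow(pulses) > 0L) cmd <- pulses$payload[1]
        }
        if (is.null(cmd)) cmd <- dstate$active_cmd
        sim <- apply_command(sim, cmd, dt)
        n_windows <- n_windows + 1L
        if (sim$completed || t_now >= timeout_s) break
      }
    }
  }
  list(completed = sim$completed,
       elapsed_s = if (sim$completed && !is.na(sim$t_start)) {
         sim$t_done - sim$t_start
       } else NA_real_,
       events = if (length(logs)) do.call(rbind, logs) else NULL,
       n_windows = n_windows, sim = sim)
}
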