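deb <- function(label, n = 5) rep(label, n)
pose_low <- c(x = 70, y = 0, z = 8)
pose_high <- c(x = 70, y = 0, z = 50)

test_that("axis selection then direction yields the mapped command", {
  labels <- c(deb("REBO"), "REST", deb("LEb", 3))
  log <- decode_stream(labels)
  expect_equal(log$payload[log$kind == "broadcast"], c("Left or right", "Left"))
  cmd <- log[log$kind == "command", ]
  expect_equal(cmd$payload[1], "+X")
  expect_equal(cmd$lifecycle[1], "start")
})

test_that("the eight canonical sequences produce the eight distinct commands", {
  pairs <- list(c("REBO", "LEb"), c("REBO", "Bk"), c("LEBO", "LEb"),
                c("LEBO", "Bk"), c("TMR", "LEb"), c("TMR", "Bk"),
                c("TML", "LEb"), c("TML", "Bk"))
  got <- character(0)
  for (p in pairs) {
    labels <- c(deb(p[1]), deb(p[2], 3), rep("REST", 8))
    log <- decode_stream(labels)
    got <- c(got, log$payload[log$kind == "command" &
                                log$lifecycle %in% c("start", "pulse")])
  }
  expect_setequal(got, command_set())
  expect_length(got, 8)
})

test_that("gripper commands follow the broadcast table and the safety guard", {
  cfg <- decoder_config()
  labels <- c(deb("TML"), deb("LEb", 3))
  log <- decode_stream(labels, cfg)  # default pose is low and over desktop
  expect_equal(log$payload[log$kind == "broadcast"], c("Gripper", "Close"))
  expect_equal(log$payload[log$kind == "command"], "close_gripper")
  expect_equal(log$lifecycle[log$kind == "command"], "pulse")
  # same sequence with the arm high: refusal, no command
  log_hi <- decode_stream(labels, cfg,
                          arm_pose_provider = function(t) pose_high)
  expect_equal(sum(log_hi$kind == "command"), 0)
  expect_equal(sum(log_hi$kind == "refusal"), 1)
  # off the desktop: refused too
  log_off <- decode_stream(labels, cfg,
                           arm_pose_provider = function(t) {
                             c(x = 5, y = 0, z = 8)
                           })
  expect_equal(sum(log_off$kind == "command"), 0)
  # swapped convention: LEb opens
  log_sw <- decode_stream(labels, decoder_config(gripper_swap = TRUE))
  expect_equal(log_sw$payload[log_sw$kind == "command"], "open_gripper")
})

test_that("the second action expires after the 5 s deadline", {
  cfg <- decoder_config()
  labels <- c(deb("LEBO"), rep("REST", 120), deb("Bk", 4))  # 6 s gap
  log <- decode_stream(labels, cfg)
  expect_equal(sum(log$kind == "command"), 0)
  # within the deadline the same stream works
  labels_ok <- c(deb("LEBO"), rep("REST", 40), deb("Bk", 3))  # 2 s gap
  log_ok <- decode_stream(labels_ok, cfg)
  expect_equal(log_ok$payload[log_ok$kind == "command"], "-Y")
})

test_that("hold-to-move stops on sustained REST but rides through blips", {
  cfg <- decoder_config()
  labels <- c(deb("TMR"), deb("LEb", 10), "REST", "REST", deb("LEb", 10),
              rep("REST", 8))
  log <- decode_stream(labels, cfg)
  cmd <- log[log$kind == "command", ]
  expect_equal(cmd$payload, c("+Z", "+Z"))
  expect_equal(cmd$lifecycle, c("start", "stop"))  # one run, no stutter
  # a stop always follows its start before any new start
  labels2 <- c(deb("TMR"), deb("LEb", 6), rep("REST", 8),
               deb("REBO"), deb("Bk", 6), rep("REST", 8))
  cmd2 <- decode_stream(labels2, cfg)
  cmd2 <- cmd2[cmd2$kind == "command", ]
  expect_equal(cmd2$lifecycle, c("start", "stop", "start", "stop"))
  expect_equal(cmd2$payload, c("+Z", "+Z", "-X", "-X"))
})

test_that("debounce requires the configured run length", {
  cfg <- decoder_config(debounce_windows = 5)
  labels <- c(rep("REBO", 4), rep("REST", 10))  # one window short
  expect_equal(nrow(decode_stream(labels, cfg)), 0)
  labels5 <- c(rep("REBO", 5), rep("REST", 10))
  expect_equal(sum(decode_stream(labels5, cfg)$kind == "broadcast"), 1)
})

test_that("exhaustive transition audit stays within the two mapping tables", {
  cfg <- decoder_config(debounce_windows = 1, second_debounce_windows = 1)
  seen_cmd <- character(0); seen_bc <- character(0)
  firsts <- c("REBO", "LEBO", "TMR", "TML", "LEb", "Bk", "REST")
  seconds <- c("REBO", "LEBO", "TMR", "TML", "LEb", "Bk", "REST")
  for (f in firsts) {
    for (s in seconds) {
      log <- decode_stream(c(f, s, rep("REST", 3)), cfg)
      seen_cmd <- c(seen_cmd, log$payload[log$kind == "command"])
      seen_bc <- c(seen_bc, log$payload[log$kind == "broadcast"])
    }
  }
  expect_setequal(unique(seen_cmd), command_set())
  expect_setequal(unique(seen_bc), broadcast_strings())
  expect_error(decoder_step(decoder_state(), "XYZ", 0, pose_low),
               "unknown movement")
})

test_that("gripper commands never appear while the arm is high", {
  cfg <- decoder_config(debounce_windows = 2)
  set.seed(60)
  for (rep_i in 1:20) {
    labels <- sample(all_labels(), 120, replace = TRUE,
                     prob = c(rep(0.1, 6), 0.4))
    log <- decode_stream(labels, cfg,
                         arm_pose_provider = function(t) pose_high)
    expect_false(any(log$payload %in% c("close_gripper", "open_gripper")))
  }
})

test_that("decoding is deterministic and returns to stage 0", {
  labels <- c(deb("TML"), deb("Bk", 3), rep("REST", 10), deb("REBO"),
              deb("LEb", 3), rep("REST", 10))
  l1 <- decode_stream(labels)
  l2 <- decode_stream(labels)
  expect_identical(l1, l2)
  # after each completed command the decoder accepts a fresh selection
  expect_equal(sum(l1$kind == "command"), 3)  # pulse + start + stop
  expect_equal(nrow(decode_stream(rep("REST", 50))), 0)
})
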