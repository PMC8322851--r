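test_that("default cross-talk profile encodes the electrode pairing", {
  p <- default_crosstalk_profile()
  expect_true(all(p$gains["REST", ] == 0))
  expect_equal(p$gains["LEb", 5], 0, ignore_attr = TRUE)
  expect_equal(sum(p$gains["LEb", ] > 0), 1)     # forehead only
  expect_true(all(p$gains["Bk", ] > 0))          # clench bleeds everywhere
  for (m in movement_labels()) {
    expect_equal(unname(which.max(p$gains[m, ])), unname(main_channel()[m]))
  }
  # amplitude ordering of the main-channel gains
  g <- vapply(movement_labels(), function(m) p$gains[m, main_channel()[m]],
              numeric(1))
  expect_true(g["Bk"] > g["LEb"])
  expect_true(g["LEb"] > g["TML"])
  expect_equal(g[["TML"]], g[["TMR"]])
  expect_true(g["TML"] > g["LEBO"])
  expect_equal(g[["LEBO"]], g[["REBO"]])
})

test_that("profile invariants are enforced", {
  g <- default_crosstalk_profile()$gains
  g["REST", 1] <- 0.1
  expect_error(crosstalk_profile(g), "REST")
  g <- default_crosstalk_profile()$gains
  g["LEb", 2] <- 0.7  # beats the main channel
  expect_error(crosstalk_profile(g), "strict maximum")
  g <- default_crosstalk_profile()$gains
  g["TML", 5] <- -1
  expect_error(crosstalk_profile(g))
})

test_that("one round has each movement once, in seeded random order", {
  r <- generate_round(round_seed = 7)
  expect_equal(nrow(r$events), 6)
  expect_setequal(r$events$label, movement_labels())
  r2 <- generate_round(round_seed = 7)
  expect_identical(r$samples, r2$samples)
  expect_identical(r$events, r2$events)
  r3 <- generate_round(round_seed = 8)
  expect_false(identical(r3$samples, r$samples))
  expect_error(generate_round(config = protocol_config(action_duration_s = 0)),
               "positive")
})

test_that("dataset generation conserves rounds and events", {
  ds <- generate_dataset(config = protocol_config(n_rounds = 3, seed = 5))
  expect_length(ds, 3)
  expect_equal(sum(vapply(ds, function(r) nrow(r$events), numeric(1))), 18)
  for (r in ds) expect_setequal(r$events$label, movement_labels())
  # distinct rounds
  expect_false(identical(ds[[1]]$samples, ds[[2]]$samples))
  ds1 <- generate_dataset(config = protocol_config(n_rounds = 1, seed = 5))
  expect_length(ds1, 1)
})

test_that("epoch RMS respects the cross-talk structure", {
  r <- generate_round(round_seed = 11)
  # each movement dominates its own main channel, except against Bk epochs
  for (m in movement_labels()) {
    ch <- main_channel()[[m]]
    own <- epoch_rms(r, m, ch)
    for (other in setdiff(movement_labels(), c(m, "Bk"))) {
      expect_gt(own, epoch_rms(r, other, ch))
    }
  }
  expect_gt(epoch_rms(r, "Bk", 4), epoch_rms(r, "REBO", 4))
})

test_that("online stream realises the intended sequence with ground truth", {
  p <- default_crosstalk_profile()
  seqd <- data.frame(label = c("REST", "REBO", "REST", "LEb"),
                     duration_s = c(2, 1.5, 1, 2.5))
  s <- generate_online_stream(p, seqd, protocol_config(seed = 3))
  expect_equal(recording_duration(s), sum(seqd$duration_s))
  # truth changes exactly at segment boundaries
  change_at <- which(s$truth[-1] != s$truth[-length(s$truth)])
  expect_equal(change_at, cumsum(seqd$duration_s * 1000)[1:3])
  # REST-only stream: per-channel RMS ~ baseline noise sd, within 20%
  rest <- generate_online_stream(p, data.frame(label = "REST",
                                               duration_s = 2),
                                 protocol_config(seed = 9))
  rms <- apply(rest$samples, 2, function(x) sqrt(mean(x^2)))
  expect_true(all(abs(rms - p$baseline_noise_sd) / p$baseline_noise_sd < 0.2))
  expect_error(generate_online_stream(p, data.frame(label = character(0),
                                                    duration_s = numeric(0))),
               "non-empty")
})
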