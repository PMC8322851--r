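test_that("axis commands move the end effector at 3 cm/s with clamping", {
  sc <- make_scenario(1)
  sim <- new_sim(sc)
  sim$pos <- c(x = 50, y = 0, z = 50)
  sim <- apply_command(sim, "+X", 1)
  expect_equal(unname(sim$pos), c(53, 0, 50))
  sim$pos <- c(x = 120, y = 0, z = 50)
  sim <- apply_command(sim, "+X", 2)
  expect_equal(unname(sim$pos[["x"]]), 120)  # clamped at the workspace edge
  expect_error(apply_command(sim, "fly"), "unknown command")
  expect_error(apply_command(sim, "+X", dt_s = 0))
})

test_that("the +Y overhang is only reachable in the mouth band", {
  sc <- make_scenario(1)
  sim <- new_sim(sc)
  sim$pos <- c(x = 30, y = 99.9, z = 80)  # outside the mouth x band
  sim <- apply_command(sim, "+Y", 2)
  expect_equal(unname(sim$pos[["y"]]), 100)
  sim$pos <- c(x = 70, y = 99.9, z = 80)  # inside the band
  sim <- apply_command(sim, "+Y", 2)
  expect_gt(sim$pos[["y"]], 100)
  sim <- apply_command(sim, "+Y", 20)
  expect_lte(sim$pos[["y"]], 130)  # 30 cm overhang at most
})

test_that("grasping requires proximity and the cup follows the gripper", {
  sc <- make_scenario(2)
  sim <- new_sim(sc)
  # far away: closing does nothing but latch the gripper
  sim <- apply_command(sim, "close_gripper")
  expect_equal(sim$gripper, "closed")
  expect_false(sim$holding_cup)
  sim <- apply_command(sim, "open_gripper")
  # teleport next to the cup (test shortcut) and close
  gp <- c(x = sc$cup_position[["x"]], y = sc$cup_position[["y"]],
          z = sc$cup_height / 2)
  sim$pos <- gp
  sim <- apply_command(sim, "close_gripper")
  expect_true(sim$holding_cup)
  expect_false(sim$cup_on_saucer)
  sim <- apply_command(sim, "+Z", 2)
  expect_equal(unname(sim$cup), unname(sim$pos))  # cup rides along
  # release away from the saucer: cup drops where it is
  sim$pos <- c(x = 30, y = -60, z = 20)
  sim$cup <- sim$pos
  sim <- apply_command(sim, "open_gripper")
  expect_false(sim$holding_cup)
  expect_false(sim$cup_on_saucer)
  expect_equal(unname(sim$cup[["z"]]), 0)
})

test_that("scenarios are seeded, constrained and reproducible", {
  for (s in 1:200) {
    sc <- make_scenario(s)
    expect_equal(unname(sc$gripper_start[["y"]]), -45)
    expect_true(sc$gripper_start[["x"]] >= 20 && sc$gripper_start[["x"]] <= 120)
    expect_true(sc$gripper_start[["z"]] >= 5 && sc$gripper_start[["z"]] <= 120)
    r <- sc$cup_diameter / 2
    expect_true(abs(sc$cup_position[["x"]] - 90) <= 15 - r)
    expect_true(abs(sc$cup_position[["y"]] - 45) <= 7.5 - r)
  }
  expect_identical(make_scenario(77), make_scenario(77))
})

test_that("the scripted policy completes in the closed-form time", {
  for (s in c(5, 17)) {
    sc <- make_scenario(s)
    res <- run_task(sc, scripted_policy(sc))
    expect_true(res$completed)
    expect_false(is.na(res$t_grasp))
    expect_true(res$t_grasp < res$t_mouth && res$t_mouth < res$t_done)
    expected <- scripted_path_length(sc) / 3
    expect_lt(abs(res$elapsed_s - expected) / expected, 0.05)
  }
})

test_that("a policy that never closes the gripper times out incomplete", {
  sc <- make_scenario(9)
  res <- run_task(sc, function(sim, t) "+Y", timeout_s = 20)
  expect_false(res$completed)
  expect_true(is.na(res$elapsed_s))
})

test_that("random command streams keep the arm inside the workspace", {
  ws <- fci_workspace()
  sc <- make_scenario(4)
  set.seed(99)
  sim <- new_sim(sc, ws)
  prev <- sim$pos
  for (i in 1:2000) {
    cmd <- sample(command_set(), 1)
    sim <- apply_command(sim, cmd, 0.05)
    p <- sim$pos
    expect_true(p[["x"]] >= 20 && p[["x"]] <= 120)
    expect_true(p[["z"]] >= 5 && p[["z"]] <= 120)
    expect_true(p[["y"]] >= -70 && p[["y"]] <= 130)
    # per-tick displacement bounded by speed * dt
    expect_lte(sqrt(sum((p - prev)^2)), 3 * 0.05 + 1e-9)
    # cup conservation: held, on the saucer, or dropped on the desktop
    states <- c(sim$holding_cup,
                sim$cup_on_saucer,
                !sim$holding_cup && !sim$cup_on_saucer &&
                  sim$cup[["z"]] == 0)
    expect_equal(sum(states), 1)
    prev <- p
  }
})
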