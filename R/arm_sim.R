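# Kinematic point model of the robotic-arm end effector and the three-stage
# drinking task: reach and grasp the cup, carry it to the mouth zone, return
# it to the saucer. The end effector moves at 3 cm/s along one Cartesian
# axis at a time inside a bounded workspace; only the +Y desktop edge may be
# overhung (by up to 30 cm) so the cup can reach the mouth.

#' Workspace geometry
#'
#' @param x_range,y_range,z_range axis ranges in cm.
#' @param mouth_x x band within which the +Y overhang (mouth zone) is
#'   reachable.
#' @param mouth_y,mouth_z mouth-zone extents in cm (y beyond the desktop
#'   edge, at most 30 cm overhang).
#' @param overhang_cm maximal +Y overhang (default 30).
#' @return an object of class `fci_workspace`.
#' @export
fci_workspace <- function(x_range = c(20, 120), y_range = c(-70, 100),
                          z_range = c(5, 120), mouth_x = c(55, 85),
                          mouth_y = c(100, 130), mouth_z = c(60, 100),
                          overhang_cm = 30) {
  stopifnot(diff(x_range) > 0, diff(y_range) > 0, diff(z_range) > 0,
            overhang_cm <= 30, mouth_y[2] <= y_range[2] + overhang_cm)
  structure(list(x_range = x_range, y_range = y_range, z_range = z_range,
                 desktop = list(x = x_range, y = y_range),
                 mouth_x = mouth_x, mouth_y = mouth_y, mouth_z = mouth_z,
                 overhang_cm = overhang_cm),
            class = "fci_workspace")
}

#' Random drinking-task scenario
#'
#' The 30 x 15 cm saucer is fixed at (90, 45, 0); the cup (7.5 cm diameter,
#' 13 cm tall) is placed at a seeded uniform position fully on the saucer;
#' the gripper starts at (x_i, -45, z_i) with x_i uniform on 20..120 cm and
#' z_i uniform on 5..120 cm.
#'
#' @param seed integer seed.
#' @return an object of class `task_scenario`.
#' @export
make_scenario <- function(seed = 1L) {
  with_seed(seed, {
    saucer_center <- c(x = 90, y = 45, z = 0)
    saucer_size <- c(30, 15)
    cup_r <- 7.5 / 2
    cup <- c(x = stats::runif(1, 90 - 15 + cup_r, 90 + 15 - cup_r),
             y = stats::runif(1, 45 - 7.5 + cup_r, 45 + 7.5 - cup_r))
    structure(list(saucer_center = saucer_center, saucer_size = saucer_size,
                   cup_position = cup, cup_diameter = 7.5, cup_height = 13,
                   gripper_start = c(x = stats::runif(1, 20, 120), y = -45,
                                     z = stats::runif(1, 5, 120)),
                   seed = as.integer(seed)),
            class = "task_scenario")
  })
}

on_saucer <- function(xy, scenario) {
  abs(xy[["x"]] - scenario$saucer_center[["x"]]) <= scenario$saucer_size[1] / 2 &&
    abs(xy[["y"]] - scenario$saucer_center[["y"]]) <= scenario$saucer_size[2] / 2
}

in_mouth_zone <- function(pos, ws) {
  pos[["x"]] >= ws$mouth_x[1] && pos[["x"]] <= ws$mouth_x[2] &&
    pos[["y"]] >= ws$mouth_y[1] && pos[["y"]] <= ws$mouth_y[2] &&
    pos[["z"]] >= ws$mouth_z[1] && pos[["z"]] <= ws$mouth_z[2]
}

# grasp point: mid-body of the cup
grasp_point <- function(scenario) {
  c(x = scenario$cup_position[["x"]], y = scenario$cup_position[["y"]],
    z = scenario$cup_height / 2)
}

#' Fresh simulator state for a scenario
#'
#' @param scenario a [make_scenario()].
#' @param workspace a [fci_workspace()].
#' @param speed_cm_s end-effector speed (default 3 cm/s).
#' @param grasp_radius_cm capture radius of the soft gripper (default 5).
#' @param drink_dwell_s time the held cup must stay in the mouth zone to
#'   count as drinking (default 1 s).
#' @return an object of class `fci_sim`.
#' @export
new_sim <- function(scenario, workspace = fci_workspace(), speed_cm_s = 3,
                    grasp_radius_cm = 5, drink_dwell_s = 1) {
  structure(list(
    pos = scenario$gripper_start, speed = speed_cm_s, gripper = "open",
    holding_cup = FALSE,
    cup = c(scenario$cup_position, z = 0), cup_on_saucer = TRUE,
    visited_mouth = FALSE, mouth_dwell = 0,
    t = 0, t_start = NA_real_, t_grasp = NA_real_, t_mouth = NA_real_,
    t_done = NA_real_, completed = FALSE,
    scenario = scenario, ws = workspace,
    grasp_radius = grasp_radius_cm, drink_dwell = drink_dwell_s),
    class = "fci_sim")
}

clamp_pos <- function(pos, ws) {
  pos[["x"]] <- min(max(pos[["x"]], ws$x_range[1]), ws$x_range[2])
  pos[["z"]] <- min(max(pos[["z"]], ws$z_range[1]), ws$z_range[2])
  y_max <- if (pos[["x"]] >= ws$mouth_x[1] && pos[["x"]] <= ws$mouth_x[2]) {
    ws$y_range[2] + ws$overhang_cm
  } else ws$y_range[2]
  pos[["y"]] <- min(max(pos[["y"]], ws$y_range[1]), y_max)
  pos
}

#' Apply one command to the simulator for dt seconds
#'
#' Axis commands translate the end effector at 3 cm/s along the signed
#' axis, clamped to the workspace (with the mouth-zone overhang on +Y);
#' `close_gripper`/`open_gripper` switch the self-locking gripper state.
#' Closing within the grasp radius of the cup picks it up; opening while
#' holding releases the cup where the gripper is (back onto the saucer if
#' over it). `NULL` advances time only.
#'
#' @param sim a [new_sim()] state.
#' @param command one of [command_set()], or `NULL` for idle.
#' @param dt_s tick duration in seconds (> 0).
#' @return the updated `fci_sim`.
#' @export
apply_command <- function(sim, command, dt_s = 0.05) {
  stopifnot(dt_s > 0)
  ws <- sim$ws
  if (!is.null(command)) {
    if (!command %in% command_set()) stop("unknown command: ", command,
                                          call. = FALSE)
    if (command %in% c("close_gripper", "open_gripper")) {
      if (command == "close_gripper") {
        sim$gripper <- "closed"
        gp <- grasp_point(sim$scenario)
        gp[c("x", "y")] <- sim$cup[c("x", "y")]
        if (!sim$holding_cup && !is.na(sim$cup[["x"]]) &&
            sqrt(sum((sim$pos - gp)^2)) <= sim$grasp_radius) {
          sim$holding_cup <- TRUE
          sim$cup_on_saucer <- FALSE
          if (is.na(sim$t_grasp)) sim$t_grasp <- sim$t
        }
      } else {
        sim$gripper <- "open"
        if (sim$holding_cup) {
          sim$holding_cup <- FALSE
          sim$cup <- c(x = sim$pos[["x"]], y = sim$pos[["y"]], z = 0)
          sim$cup_on_saucer <- on_saucer(sim$cup, sim$scenario)
        }
      }
    } else {
      axis <- substr(command, 2, 2)
      sgn <- if (substr(command, 1, 1) == "+") 1 else -1
      if (is.na(sim$t_start)) sim$t_start <- sim$t
      p <- sim$pos
      p[[tolower(axis)]] <- p[[tolower(axis)]] + sgn * sim$speed * dt_s
      sim$pos <- clamp_pos(p, ws)
      if (sim$holding_cup) sim$cup <- sim$pos
    }
  }
  sim$t <- sim$t + dt_s
  if (sim$holding_cup && in_mouth_zone(sim$pos, ws)) {
    sim$mouth_dwell <- sim$mouth_dwell + dt_s
    if (!sim$visited_mouth && sim$mouth_dwell >= sim$drink_dwell) {
      sim$visited_mouth <- TRUE
      sim$t_mouth <- sim$t
    }
  }
  if (sim$visited_mouth && sim$cup_on_saucer && !sim$holding_cup &&
      !sim$completed) {
    sim$completed <- TRUE
    sim$t_done <- sim$t
  }
  sim
}

#' Run the drinking task under a command policy
#'
#' Integrates the simulator at `dt_s` ticks; the policy is called each tick
#' with the current state and may return a command (held for that tick) or
#' `NULL`. The task clock starts when the gripper first moves and stops
#' when the cup is back on the saucer after the mouth visit.
#'
#' @param scenario a [make_scenario()].
#' @param policy function(sim, t) -> command or `NULL`.
#' @param timeout_s wall limit in simulated seconds (default 600).
#' @param dt_s tick (default 0.05 s, the decoder cadence).
#' @param workspace a [fci_workspace()].
#' @return list: `completed`, `elapsed_s` (NA if never started or not
#'   completed), `t_grasp`, `t_mouth`, `t_done`, and the final `sim`.
#' @export
run_task <- function(scenario, policy, timeout_s = 600, dt_s = 0.05,
                     workspace = fci_workspace()) {
  sim <- new_sim(scenario, workspace)
  while (sim$t < timeout_s && !sim$completed) {
    sim <- apply_command(sim, policy(sim, sim$t), dt_s)
  }
  list(completed = sim$completed,
       elapsed_s = if (sim$completed && !is.na(sim$t_start)) {
         sim$t_done - sim$t_start
       } else NA_real_,
       t_grasp = sim$t_grasp, t_mouth = sim$t_mouth, t_done = sim$t_done,
       sim = sim)
}

# which single-axis command moves pos toward target on the given axis
axis_command_toward <- function(pos, target, axis, tol) {
  d <- target[[axis]] - pos[[axis]]
  if (abs(d) <= tol) return(NULL)
  paste0(if (d > 0) "+" else "-", toupper(axis))
}

#' Scripted button policy for the drinking task
#'
#' The deterministic "virtual button" solver: align x then y then z to the
#' cup and close; rise, move over the mouth band, push into the mouth zone
#' and dwell; then retrace to the saucer and open. Its elapsed time is the
#' Manhattan path length divided by the 3 cm/s speed plus the drinking
#' dwell.
#'
#' @param scenario a [make_scenario()].
#' @param workspace a [fci_workspace()].
#' @return function(sim, t) usable with [run_task()].
#' @export
scripted_policy <- function(scenario, workspace = fci_workspace()) {
  mouth <- c(x = mean(workspace$mouth_x), y = mean(workspace$mouth_y),
             z = mean(workspace$mouth_z))
  tol <- 0.08  # just over half a 50 ms step at 3 cm/s
  phase <- new.env(parent = emptyenv())
  phase$now <- "fetch"
  function(sim, t) {
    gp <- grasp_point(scenario)
    if (phase$now == "fetch") {
      for (ax in c("x", "y", "z")) {
        cmd <- axis_command_toward(sim$pos, gp, ax, tol)
        if (!is.null(cmd)) return(cmd)
      }
      if (!sim$holding_cup) return("close_gripper")
      phase$now <- "to_mouth"
    }
    if (phase$now == "to_mouth") {
      # rise first, then x into the mouth band, then push +Y to the centre
      for (ax in c("z", "x", "y")) {
        cmd <- axis_command_toward(sim$pos, mouth, ax, tol)
        if (!is.null(cmd)) return(cmd)
      }
      if (!sim$visited_mouth) return(NULL)  # dwell to drink
      phase$now <- "return"
    }
    if (phase$now == "return") {
      # retrace: y back over the saucer, then x, then down
      for (ax in c("y", "x", "z")) {
        cmd <- axis_command_toward(sim$pos, gp, ax, tol)
        if (!is.null(cmd)) return(cmd)
      }
      return("open_gripper")
    }
    NULL
  }
}

#' Manhattan path length of the scripted solution
#'
#' Closed-form length (cm) of the scripted policy's path: start to grasp
#' point, grasp point to mouth centre, and back. Dividing by the 3 cm/s
#' speed and adding the drinking dwell gives the expected elapsed time.
#'
#' @param scenario a [make_scenario()].
#' @param workspace a [fci_workspace()].
#' @return numeric length in cm.
#' @export
scripted_path_length <- function(scenario, workspace = fci_workspace()) {
  gp <- grasp_point(scenario)
  mouth <- c(x = mean(workspace$mouth_x), y = mean(workspace$mouth_y),
             z = mean(workspace$mouth_z))
  l1 <- function(a, b) sum(abs(a[c("x", "y", "z")] - b[c("x", "y", "z")]))
  l1(scenario$gripper_start, gp) + l1(gp, mouth) + l1(mouth, gp)
}
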