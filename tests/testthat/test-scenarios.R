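test_that("packaged configs load, validate and round-trip through YAML", {
  for (nm in c("toy", "forward", "sideways", "cross_body",
               "forward_perturbed")) {
    cfg <- scenario_config(nm)
    expect_identical(cfg$scenario, nm)
    tmp <- tempfile(fileext = ".yaml")
    yaml::write_yaml(unclass(cfg), tmp)
    cfg2 <- scenario_config(tmp)
    expect_equal(unclass(cfg2), unclass(cfg))
  }
  expect_error(scenario_config("backflip"), "valid names")
  expect_error(scenario_config("forward", list(dt = -1)), "dt")
  expect_error(scenario_config("forward", list(gains = list(Kp = 1))), "Kp")
})

test_that("overrides merge recursively into a config", {
  cfg <- scenario_config("forward", list(reach = list(T = 0.3),
                                         gains = list(Kd = c(9, 9, 9))))
  expect_equal(cfg$reach$T, 0.3)
  expect_equal(cfg$gains$Kd, c(9, 9, 9))
  expect_equal(cfg$reach$target, c(0.05, 0.50))   # untouched sibling keys
  expect_equal(cfg$gains$Kp, c(60, 60, 60))
})

test_that("inverse kinematics places the fingertip on the target", {
  model <- arm_model()
  q0 <- c(10, 120, 0) * pi / 180
  for (target in list(c(0.05, 0.50), c(0.45, 0.15), c(-0.30, 0.35))) {
    qf <- reach_ik(model, target, wrist_final = -0.15, q0 = q0)
    hand <- hand_kinematics(model, arm_state(qf))$position
    expect_equal(hand, target, tolerance = 1e-10)
    expect_equal(qf[3], -0.15)
  }
  expect_error(reach_ik(model, c(2, 2), -0.15, q0), "unreachable")
})

test_that("the forward reach arrives within 1 cm by 0.5 s and stays", {
  fw <- forward_run()
  expect_false(is.na(fw$meta$reach_time))
  expect_lte(fw$meta$reach_time, 0.5)
  d <- fw$meta$hand_target_distance
  expect_true(all(d[fw$time >= fw$meta$reach_time] < 0.01))
})

test_that("forward-reach roles: shoulder flexes, elbow and wrist extend", {
  fw <- forward_run()
  expect_identical(select_agonist(fw, "shoulder")$role, "flexor")
  expect_identical(select_agonist(fw, "elbow")$role, "extensor")
  expect_identical(select_agonist(fw, "wrist")$role, "extensor")
})

test_that("the shoulder traverses joint-FV space clockwise through I, IV, III, II", {
  fw <- forward_run()
  m <- trajectory_metrics(extract_trajectory(fw, "shoulder"))
  expect_identical(m$rotation, "clockwise")
  qs <- m$quadrant_sequence
  expect_identical(qs[1:2], c("I", "IV"))
  expect_true(all(c("III", "II") %in% qs))
  expect_gt(which("III" == qs)[1], 2)
})

test_that("co-contraction emerges during the reach despite one-sided excitation", {
  fw <- forward_run()
  per_joint_exc <- sapply(fw$joints, function(j) {
    cols <- grep(paste0("^", j, "_"), fw$muscle_names)
    min(apply(fw$excitation[, cols] > 0, 1, sum) <= 1)
  })
  expect_true(all(per_joint_exc == 1))  # never both muscles excited at once
  act <- fw$activation
  co <- pmin(act[, "shoulder_flexor"], act[, "shoulder_extensor"])
  expect_gt(max(co), 0.02)              # but activations overlap (lag)
})

test_that("the perturbed reach still completes and spikes the elbow torque rate", {
  fw <- forward_run()
  fp <- perturbed_run()
  expect_false(is.na(fp$meta$reach_time))
  expect_lte(fp$meta$reach_time, 0.5)
  on <- fp$ext_force[, 1] != 0 | fp$ext_force[, 2] != 0
  expect_gt(sum(on), 0)
  mag <- sqrt(rowSums(fp$ext_force[on, , drop = FALSE]^2))
  expect_equal(mag, rep(100, length(mag)))
  dot <- rowSums(fp$ext_force[on, , drop = FALSE] *
                   fp$hand_vel[on, , drop = FALSE])
  expect_equal(max(abs(dot)), 0, tolerance = 1e-9)
  peak_rate <- function(r) {
    max(abs(diff(r$torque_net[, "elbow"]) / diff(r$time)))
  }
  expect_gt(peak_rate(fp), peak_rate(fw))
})

test_that("the toy scenario yields time-aligned plan and tracked variants", {
  toy <- toy_run()
  expect_s3_class(toy, "toy_result")
  expect_identical(toy$plan$time, toy$tracked$time)
  expect_identical(toy$plan$muscle_names, toy$tracked$muscle_names)
})
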