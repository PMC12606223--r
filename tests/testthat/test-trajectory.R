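test_that("fixture kinds are deterministic and shaped as documented", {
  f1 <- generate_fixture("biphasic_reach", seed = 4, noise = 0.02)
  f2 <- generate_fixture("biphasic_reach", seed = 4, noise = 0.02)
  expect_identical(f1$activation, f2$activation)
  f3 <- generate_fixture("biphasic_reach", seed = 5, noise = 0.02)
  expect_false(identical(f1$activation, f3$activation))
  expect_error(generate_fixture("nonsense"), "unknown kind")
  expect_error(generate_fixture("single_muscle", n_steps = 2))
  # two-hump velocity profile
  v <- generate_fixture("biphasic_reach")$v_norm[, "joint_flexor"]
  peaks <- which(diff(sign(diff(v))) < 0 & v[-c(1, length(v))] > 0.05)
  expect_length(peaks, 2)
})

test_that("the single-muscle fixture trajectory lies on the scaled FV curve", {
  fx <- generate_fixture("single_muscle")
  p <- fx$muscle_params[["joint_flexor"]]
  tr <- extract_trajectory(fx, "joint", "joint_flexor")
  expect_equal(tr$f, 0.7 * fv_gain(tr$v, p), tolerance = 1e-12)
})

test_that("the co-activated fixture trajectory is odd-symmetric", {
  fx <- generate_fixture("coactivated", n_steps = 501)
  tr <- extract_trajectory(fx, "joint", "joint_flexor")
  # samples half a period apart carry opposite velocity and torque
  k <- 1:250
  expect_equal(tr$v[k + 250], -tr$v[k], tolerance = 1e-9)
  expect_equal(tr$f[k + 250], -tr$f[k], tolerance = 1e-9)
})

test_that("agonist selection follows early positive mechanical power", {
  fx <- generate_fixture("single_muscle")
  sel <- select_agonist(fx, "joint")
  expect_identical(sel$role, "flexor")
  expect_identical(sel$sign, 1)
  toy <- toy_run()
  expect_identical(select_agonist(toy$tracked, "joint")$role, "flexor")
  # a quiescent simulation has no agonist
  still <- simulate_joint(0.05,
                          list(flexor = fv_params(), extensor = fv_params()),
                          function(t, q, qdot) c(0, 0), duration = 0.1,
                          dt = 1e-3)
  expect_error(select_agonist(still, "joint"), "ambiguous")
})

test_that("trajectories from a quiescent simulation sit on-axis at the origin", {
  still <- simulate_joint(0.05,
                          list(flexor = fv_params(), extensor = fv_params()),
                          function(t, q, qdot) c(0, 0), duration = 0.1,
                          dt = 1e-3)
  tr <- extract_trajectory(still, "joint", "joint_flexor")
  expect_true(all(tr$quadrant == "on-axis"))
  expect_true(all(tr$v == 0 & tr$f == 0))
  expect_error(extract_trajectory(still, "elbow"), "unknown joint")
})

test_that("trajectory metrics recover the geometry of a known loop", {
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  cw <- data.frame(v = cos(-th), f = sin(-th))      # clockwise unit circle
  m <- trajectory_metrics(cw)
  expect_identical(m$rotation, "clockwise")
  expect_lt(m$signed_area, 0)
  expect_equal(abs(m$signed_area), pi, tolerance = 0.01)
  expect_identical(m$quadrant_sequence, c("IV", "III", "II", "I"))
  expect_equal(m$x_crossings, 1)   # the implicit closing edge is not counted
  expect_lt(m$closure_distance, 0.1)
  ccw <- data.frame(v = cos(th), f = sin(th))
  expect_identical(trajectory_metrics(ccw)$rotation, "anticlockwise")
  expect_error(trajectory_metrics(cw[1:2, ]), "3 points")
})

test_that("metrics are invariant under uniform torque rescaling", {
  fx <- generate_fixture("biphasic_reach")
  tr <- extract_trajectory(fx, "joint", "joint_flexor")
  m1 <- trajectory_metrics(tr)
  for (s in c(0.25, 4)) {
    tr2 <- data.frame(v = tr$v, f = s * tr$f)
    m2 <- trajectory_metrics(tr2)
    expect_identical(m2$quadrant_sequence, m1$quadrant_sequence)
    expect_identical(m2$rotation, m1$rotation)
    expect_identical(m2$x_crossings, m1$x_crossings)
  }
})

test_that("external tabular series round-trip through as_sim_result", {
  fx <- generate_fixture("biphasic_reach", n_steps = 101)
  long <- do.call(rbind, lapply(fx$muscle_names, function(m) {
    data.frame(time = fx$time, joint = "joint", muscle = m,
               angle = fx$q[, 1], velocity = fx$qdot[, 1],
               activation = fx$activation[, m], torque = fx$torque[, m])
  }))
  res <- as_sim_result(long, fx$muscle_params, c(joint = 1))
  expect_equal(res$torque_net[, 1], fx$torque_net[, 1])
  tr1 <- extract_trajectory(fx, "joint", "joint_flexor")
  tr2 <- extract_trajectory(res, "joint", "joint_flexor")
  expect_equal(tr2$v, tr1$v)
  expect_equal(tr2$f, tr1$f)
  expect_error(as_sim_result(long[, -4], fx$muscle_params),
               "missing column")
})
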