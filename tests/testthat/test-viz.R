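test_that("joint-FV frames respect the rest start and index bounds", {
  fw <- forward_run()
  p <- render_joint_fv_frame(fw, "shoulder", 1)
  expect_s3_class(p, "ggplot")
  tr <- extract_trajectory(fw, "shoulder")
  expect_equal(tr$v[1], 0)   # simulations start at rest: origin point
  expect_equal(tr$f[1], 0)
  expect_error(render_joint_fv_frame(fw, "shoulder", 0), "outside")
  expect_error(render_joint_fv_frame(fw, "shoulder", 1e9), "outside")
})

test_that("the operating point lies on the instantaneous joint-fv curve", {
  fw <- forward_run()
  idx <- round(seq(1, length(fw$time), length.out = 7))
  for (i in idx) {
    expect_no_warning(render_joint_fv_frame(fw, "elbow", i, inset = FALSE))
  }
})

test_that("with a silent antagonist the current curve equals the ceiling", {
  fx <- generate_fixture("single_muscle")
  p <- fx$muscle_params[["joint_flexor"]]
  pair <- activation_pair(0.7, 0)
  cur <- joint_fv_curve(pair, p)
  expect_equal(cur$samples$f, cur$samples$ceiling)
})

test_that("frame rendering is deterministic", {
  fx <- generate_fixture("biphasic_reach", n_steps = 101)
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  save_frame(render_joint_fv_frame(fx, "joint", 50, agonist = "joint_flexor"),
             f1)
  save_frame(render_joint_fv_frame(fx, "joint", 50, agonist = "joint_flexor"),
             f2)
  expect_gt(file.size(f1), 0)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the joint-fv space area is monotone in either activation", {
  p <- fv_params()
  lv <- seq(0.1, 1, by = 0.3)
  a_fixed <- 0.6
  ag_sweep <- vapply(lv, function(a) {
    joint_fv_space_area(activation_pair(a, a_fixed), p)
  }, numeric(1))
  ant_sweep <- vapply(lv, function(a) {
    joint_fv_space_area(activation_pair(a_fixed, a), p)
  }, numeric(1))
  expect_true(all(diff(ag_sweep) > 0))
  expect_true(all(diff(ant_sweep) > 0))
})

test_that("animation writes ceil(duration * fps) fixed-axis frames", {
  fx <- generate_fixture("biphasic_reach", n_steps = 101)   # 0.5 s
  dir <- file.path(tempdir(), "anim_frames")
  info <- animate_joint_fv(fx, "joint", fps = 10, out = dir)
  expect_length(info$frames, ceiling(0.5 * 10))
  expect_true(all(file.exists(info$frames)))
  expect_true(all(file.size(info$frames) > 0))
  short <- generate_fixture("biphasic_reach", n_steps = 3)
  one <- sim_result(
    time = 0, q = matrix(0), qdot = matrix(0), qddot = matrix(0),
    excitation = matrix(0, 1, 2), activation = matrix(0, 1, 2),
    torque = matrix(0, 1, 2), force_norm = matrix(0, 1, 2),
    v_norm = matrix(0, 1, 2), torque_net = matrix(0),
    joints = "joint", muscle_names = short$muscle_names,
    muscle_sign = short$muscle_sign, muscle_params = short$muscle_params,
    flexion_sign = short$flexion_sign)
  expect_error(animate_joint_fv(one, "joint", out = dir), "fewer than 2")
})

test_that("time-series panels expose the requested series", {
  fx <- generate_fixture("biphasic_reach", n_steps = 101)
  p <- plot_time_series(fx, c("activation", "torque", "torque_rate"))
  expect_s3_class(p, "ggplot")
  expect_error(plot_time_series(fx, c("activation", "sparkles")),
               "unknown panel")
  # the torque-rate panel is the finite-difference derivative of net torque
  df <- p$data
  tr <- df[df$panel == "torque rate (N m/s)" & df$joint == "joint", ]
  dtv <- diff(fx$time)
  expect_equal(tr$value[-1], diff(fx$torque_net[, 1]) / dtv,
               tolerance = 1e-12)
  # flat input yields flat angle panel
  still <- simulate_joint(0.05,
                          list(flexor = fv_params(), extensor = fv_params()),
                          function(t, q, qdot) c(0, 0), duration = 0.05,
                          dt = 1e-3)
  p2 <- plot_time_series(still, "angle")
  expect_true(all(p2$data$value == 0))
})
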