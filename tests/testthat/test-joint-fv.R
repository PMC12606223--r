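test_that("joint-fv value reduces to the scaled agonist curve without antagonist", {
  p <- fv_params()
  v <- seq(-1, 1, length.out = 101)
  for (a in c(0.3, 1)) {
    expect_equal(joint_fv_value(v, activation_pair(a, 0), p),
                 a * fv_gain(v, p))
  }
  expect_equal(joint_fv_value(0, activation_pair(1, 1), p), 0)
  expect_equal(joint_fv_value(0, activation_pair(1, 0.5), p), 0.5)
})

test_that("equal co-activation of identical muscles gives an odd-symmetric curve", {
  p <- fv_params()
  v <- seq(0.01, 1, length.out = 50)
  for (a in c(0.4, 1)) {
    pr <- activation_pair(a, a, b = 1)
    expect_equal(joint_fv_value(-v, pr, p), -joint_fv_value(v, pr, p),
                 tolerance = 1e-12)
    expect_equal(joint_fv_value(0, pr, p), 0)
  }
})

test_that("joint-fv curves stay between floor and ceiling and pass through (0, a_net)", {
  p <- fv_params()
  set.seed(42)
  for (i in 1:100) {
    pr <- activation_pair(runif(1), runif(1), b = runif(1, 0.5, 2))
    cur <- joint_fv_curve(pr, p)
    s <- cur$samples
    expect_equal(nrow(s), 401)
    expect_true(all(s$f >= s$floor - 1e-12))
    expect_true(all(s$f <= s$ceiling + 1e-12))
    nac <- net_and_coactivation(pr)
    expect_equal(s$f[s$v == 0], nac$a_net)
  }
})

test_that("extreme activation pairs collapse the curve onto a bound", {
  p <- fv_params()
  top <- joint_fv_curve(activation_pair(1, 0), p)$samples
  expect_equal(top$f, top$ceiling)
  bot <- joint_fv_curve(activation_pair(0, 1), p)$samples
  expect_equal(bot$f, bot$floor)
  expect_error(joint_fv_curve(activation_pair(1, 0), p, grid = numeric(0)),
               "grid")
})

test_that("net activation and co-activation follow the weighting rule", {
  expect_equal(net_and_coactivation(activation_pair(1, 0)),
               list(a_net = 1, co_activation = 0))
  expect_equal(net_and_coactivation(activation_pair(1, 1)),
               list(a_net = 0, co_activation = 1))
  expect_equal(net_and_coactivation(activation_pair(0.8, 0.5)),
               list(a_net = 0.3, co_activation = 0.5))
  # unequal strengths weight the antagonist by b
  expect_equal(net_and_coactivation(activation_pair(0.9, 0.5, b = 0.5)),
               list(a_net = 0.65, co_activation = 0.25))
})

test_that("strength ratio b is the isometric torque ratio", {
  ag <- fv_params(v_max = 1, r = 0.05, F_max = 600)
  ant <- fv_params(v_max = 1, r = 0.04, F_max = 300)
  expect_equal(strength_ratio(ant, ag), (300 * 0.04) / (600 * 0.05))
  expect_equal(strength_ratio(ag, ag), 1)
})

test_that("quadrants encode power generation vs braking in each direction", {
  expect_identical(classify_quadrant(0.3, 0.5), "I")     # agonist powering
  expect_identical(classify_quadrant(0.3, -0.2), "IV")   # braking
  expect_identical(classify_quadrant(-0.3, -0.2), "III")
  expect_identical(classify_quadrant(-0.3, 0.5), "II")
  expect_identical(classify_quadrant(0, 0.4), "on-axis") # isometric
  expect_identical(classify_quadrant(0.4, 5e-4), "on-axis")
  expect_identical(classify_quadrant(c(0.3, -0.3), c(0.5, 0.5)),
                   c("I", "II"))
})

test_that("one-sided slopes at rest match the analytic branch derivatives", {
  p <- fv_params()
  single <- activation_pair(1, 0)
  expect_equal(local_slope(0, single, p, side = "right"), -(1 + p$d1))  # -5
  expect_equal(local_slope(0, single, p, side = "left"),
               -(p$d2 - 1) * (1 + p$d3))                              # -24.992
  # full co-activation adds the two branch slopes on each side
  both <- activation_pair(1, 1, b = 1)
  expect_equal(local_slope(0, both, p, side = "right"),
               -(1 + p$d1) - (p$d2 - 1) * (1 + p$d3))
  expect_equal(local_slope(0, both, p, side = "left"),
               -(1 + p$d1) - (p$d2 - 1) * (1 + p$d3))
})

test_that("local slope agrees with a finite-difference oracle off the kink", {
  p <- fv_params()
  set.seed(11)
  vs <- c(-0.7, -0.3, -0.05, 0.05, 0.4, 0.9)
  h <- 1e-6
  for (i in 1:20) {
    pr <- activation_pair(runif(1), runif(1), b = runif(1, 0.5, 2))
    for (v in vs) {
      fd <- (joint_fv_value(v + h, pr, p) - joint_fv_value(v - h, pr, p)) /
        (2 * h)
      expect_equal(local_slope(v, pr, p, side = "right"), fd,
                   tolerance = 1e-6)
    }
  }
})

test_that("co-contraction monotonically steepens the slope at rest", {
  p <- fv_params()
  for (a_ag in c(0.5, 1)) {
    slopes <- vapply(seq(0, 1, by = 0.1), function(a_ant) {
      abs(local_slope(0, activation_pair(a_ag, a_ant), p, side = "right"))
    }, numeric(1))
    expect_true(all(diff(slopes) >= 0))
    expect_gt(slopes[2], slopes[1])   # any antagonist activation steepens
    expect_equal(slopes[1],
                 abs(a_ag * fv_gain_slope(0, p, "right")))
  }
})
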