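test_that("a gravity-free chain at rest with no torque stays at rest", {
  m <- arm_model()
  expect_equal(forward_dynamics(m, arm_state(c(0.5, 1.0, -0.3)), c(0, 0, 0)),
               c(0, 0, 0))
})

test_that("with negligible distal segments the shoulder behaves as a pendulum", {
  m <- arm_model(lengths = c(0.3, 1e-3, 1e-3), masses = c(2, 1e-6, 1e-6))
  qdd <- forward_dynamics(m, arm_state(c(0.7, 0.2, 0.1)), c(1, 0, 0))
  I_total <- m$inertia[1] + m$masses[1] * m$com[1]^2   # about the pivot
  expect_equal(qdd[1], 1 / I_total, tolerance = 1e-4)
})

test_that("forward dynamics matches the independent Lagrangian oracle", {
  m <- arm_model()
  set.seed(123)
  for (i in 1:100) {
    q <- runif(3, -pi, pi)
    qd <- runif(3, -3, 3)
    tau <- runif(3, -5, 5)
    fe <- runif(2, -30, 30)
    got <- forward_dynamics(m, arm_state(q, qd), tau, fe)
    want <- oracle_forward_dynamics(m, q, qd, tau, fe)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("mass matrix is symmetric positive definite at random configurations", {
  m <- arm_model()
  set.seed(5)
  for (i in 1:25) {
    M <- mass_matrix(m, runif(3, -pi, pi))
    expect_equal(M, t(M))
    expect_gt(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("dM/dt - 2C is skew-symmetric (multibody identity)", {
  m <- arm_model()
  set.seed(9)
  h <- 1e-6
  for (i in 1:25) {
    q <- runif(3, -pi, pi); qd <- runif(3, -3, 3)
    Mdot <- (mass_matrix(m, q + h * qd) - mass_matrix(m, q - h * qd)) / (2 * h)
    S <- Mdot - 2 * coriolis_matrix(m, q, qd)
    expect_lt(max(abs(S + t(S))), 1e-8)
  }
})

test_that("hand kinematics are consistent with finite differences", {
  m <- arm_model()
  straight <- hand_kinematics(m, arm_state(c(0, 0, 0)))
  expect_equal(straight$position, m$anchor + c(sum(m$lengths), 0))
  expect_equal(straight$velocity, c(0, 0))
  set.seed(21)
  h <- 1e-7
  for (i in 1:10) {
    q <- runif(3, -pi, pi); qd <- runif(3, -3, 3)
    hk <- hand_kinematics(m, arm_state(q, qd))
    Jfd <- sapply(1:3, function(j) {
      e <- c(0, 0, 0); e[j] <- h
      (hand_kinematics(m, arm_state(q + e))$position -
         hand_kinematics(m, arm_state(q - e))$position) / (2 * h)
    })
    expect_equal(hk$jacobian, Jfd, tolerance = 1e-6)
    expect_equal(hk$velocity, as.numeric(hk$jacobian %*% qd))
  }
})

test_that("passive swings conserve kinetic energy and angular momentum", {
  res <- passive_run()
  model <- arm_model()
  n <- length(res$time)
  idx <- c(1L, n %/% 2L, n)
  E <- vapply(idx, function(i) {
    kinetic_energy(model, arm_state(res$q[i, ], res$qdot[i, ]))
  }, numeric(1))
  expect_lt(max(abs(E - E[1])) / E[1], 1e-6)
  H <- vapply(idx, function(i) {
    angular_momentum(model, arm_state(res$q[i, ], res$qdot[i, ]))
  }, numeric(1))
  expect_lt(max(abs(H - H[1])) / abs(H[1]), 1e-6)
})

test_that("halving the step shrinks the integration error ~16x (RK4 order)", {
  model <- arm_model()
  zero <- function(t, q, qdot) rep(0, 6)
  init <- arm_state(c(0.3, 1.2, -0.1), c(1, -2, 1.5))
  final <- function(dt) {
    r <- suppressWarnings(
      simulate_arm(model, zero, duration = 0.2, dt = dt, init = init))
    n <- length(r$time)
    c(r$q[n, ], r$qdot[n, ])
  }
  x1 <- final(2e-3); x2 <- final(1e-3); x3 <- final(5e-4)
  d1 <- max(abs(x1 - x2)); d2 <- max(abs(x2 - x3))
  expect_gt(d1 / d2, 10)
  expect_lt(d1 / d2, 24)
})

test_that("simulations are deterministic and hold a quiescent arm still", {
  model <- arm_model()
  zero <- function(t, q, qdot) rep(0, 6)
  still <- simulate_arm(model, zero, duration = 0.02, dt = 1e-3,
                        init = arm_state(c(0.4, 0.8, 0)))
  expect_equal(max(abs(sweep(still$q, 2L, still$q[1L, ]))), 0)
  ctrl <- function(t, q, qdot) rep(0.3, 6)
  r1 <- simulate_arm(model, ctrl, duration = 0.02, dt = 1e-3)
  r2 <- simulate_arm(model, ctrl, duration = 0.02, dt = 1e-3)
  expect_identical(r1$q, r2$q)
  expect_identical(r1$activation, r2$activation)
})

test_that("perturbation force is gated, scaled and velocity-orthogonal", {
  p <- perturbation(magnitude = 100, onset = 0.15, duration = 0.01)
  expect_identical(perturbation_force(p, 0.1, c(1, 0)), c(0, 0))
  expect_identical(perturbation_force(p, 0.2, c(1, 0)), c(0, 0))
  set.seed(3)
  for (i in 1:10) {
    hv <- runif(2, -2, 2)
    f <- perturbation_force(p, 0.155, hv)
    expect_equal(sqrt(sum(f^2)), 100)
    expect_equal(sum(f * hv), 0, tolerance = 1e-10)
    # +90 degrees anticlockwise: cross product hv x f is positive
    expect_gt(hv[1] * f[2] - hv[2] * f[1], 0)
  }
  expect_warning(f0 <- perturbation_force(p, 0.155, c(0, 0)), "fallback")
  expect_equal(sqrt(sum(f0^2)), 100)
})
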