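# Independent Lagrangian oracle for the planar 3-link chain.
#
# Kinematics are re-derived here from scratch: centre-of-mass positions come
# from cumulative complex rotations, velocities from a complex-step
# directional derivative of the position map (machine-accurate, no
# subtractive cancellation), and the equations of motion from the
# Euler-Lagrange form
#   M(q) qddot + (d2T/dqdot dq) qdot - dT/dq = tau + Jhand' F
# with every derivative of the kinetic energy T(q, qdot) taken numerically.
# Nothing is shared with the package's Jacobian/Christoffel implementation.

oracle_com_positions <- function(model, q) {
  th <- cumsum(q)
  prox_x <- cumsum(c(0, model$lengths * cos(th)))[1:3] + model$anchor[1]
  prox_y <- cumsum(c(0, model$lengths * sin(th)))[1:3] + model$anchor[2]
  list(x = prox_x + model$com * cos(th), y = prox_y + model$com * sin(th))
}

# directional derivative d/ds p(q + s * dir) at s = 0, via complex step
oracle_com_velocities <- function(model, q, qdot, eps = 1e-20) {
  qc <- q + (0+1i) * eps * qdot
  th <- cumsum(qc)
  prox_x <- cumsum(c(0, model$lengths * cos(th)))[1:3]
  prox_y <- cumsum(c(0, model$lengths * sin(th)))[1:3]
  list(vx = Im(prox_x + model$com * cos(th)) / eps,
       vy = Im(prox_y + model$com * sin(th)) / eps)
}

oracle_kinetic_energy <- function(model, q, qdot) {
  v <- oracle_com_velocities(model, q, qdot)
  thdot <- cumsum(qdot)
  sum(model$masses * (v$vx^2 + v$vy^2)) / 2 +
    sum(model$inertia * thdot^2) / 2
}

oracle_hand_jacobian <- function(model, q, eps = 1e-20) {
  sapply(1:3, function(j) {
    dir <- c(0, 0, 0); dir[j] <- 1
    qc <- q + (0+1i) * eps * dir
    th <- cumsum(qc)
    c(Im(sum(model$lengths * cos(th))), Im(sum(model$lengths * sin(th)))) / eps
  })
}

oracle_forward_dynamics <- function(model, q, qdot, tau, fext = c(0, 0),
                                    hq = 1e-3) {
  Tfun <- function(qq, qqd) oracle_kinetic_energy(model, qq, qqd)
  ej <- diag(3)
  # T is exactly quadratic in qdot, so unit-step central differences are exact
  M <- matrix(0, 3, 3)
  for (j in 1:3) for (k in 1:3) {
    M[j, k] <- (Tfun(q, qdot + ej[, j] + ej[, k]) -
                  Tfun(q, qdot + ej[, j] - ej[, k]) -
                  Tfun(q, qdot - ej[, j] + ej[, k]) +
                  Tfun(q, qdot - ej[, j] - ej[, k])) / 4
  }
  # dT/dqdot_j (exact: linear in qdot), then Richardson-extrapolated central
  # differences in q_k (h^4 accurate, large enough steps to avoid roundoff)
  dTdqd <- function(qq) {
    vapply(1:3, function(j) {
      (Tfun(qq, qdot + ej[, j]) - Tfun(qq, qdot - ej[, j])) / 2
    }, numeric(1))
  }
  rich <- function(f, h) (4 * f(h / 2) - f(h)) / 3
  G <- sapply(1:3, function(k) {
    rich(function(h) (dTdqd(q + h * ej[, k]) - dTdqd(q - h * ej[, k])) /
           (2 * h), hq)
  })  # G[j, k] = d2T / dqdot_j dq_k
  dTdq <- vapply(1:3, function(k) {
    rich(function(h) (Tfun(q + h * ej[, k], qdot) -
                        Tfun(q - h * ej[, k], qdot)) / (2 * h), hq)
  }, numeric(1))
  gen <- tau + as.numeric(t(oracle_hand_jacobian(model, q)) %*% fext)
  as.numeric(solve(M, gen - G %*% qdot + dTdq))
}
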