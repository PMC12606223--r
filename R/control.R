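#' Minimum-jerk joint-space reference trajectory
#'
#' The canonical bell-shaped-velocity reach plan: each joint angle follows
#' the quintic `q_start + (q_end - q_start) * (10 s^3 - 15 s^4 + 6 s^5)`
#' with `s = t/T`. Velocity and acceleration are zero at both ends, the
#' speed profile has a single interior maximum of `1.875 * |q_end -
#' q_start| / T` at `t = T/2`, and the pose is held at `q_end` for `t > T`.
#'
#' @param q_start,q_end Start and end joint angles in rad (equal-length
#'   numeric vectors).
#' @param T Movement duration in s (> 0).
#' @return An object of class `reference_trajectory` whose `eval` element is
#'   a function `t -> list(q, qdot, qddot)` (matrices with one row per `t`).
#' @export
minimum_jerk_reference <- function(q_start, q_end, T) {
  stopifnot(is.numeric(q_start), is.numeric(q_end),
            length(q_start) == length(q_end),
            is.numeric(T), length(T) == 1L)
  if (!is.finite(T) || T <= 0) {
    stop("minimum_jerk_reference: `T` must be positive", call. = FALSE)
  }
  dq <- q_end - q_start
  nj <- length(q_start)
  eval_fun <- function(t) {
    s <- pmin(pmax(t / T, 0), 1)
    pos <- 10 * s^3 - 15 * s^4 + 6 * s^5
    vel <- (30 * s^2 - 60 * s^3 + 30 * s^4) / T
    acc <- (60 * s - 180 * s^2 + 120 * s^3) / T^2
    list(q = outer(pos, dq) + matrix(q_start, length(t), nj, byrow = TRUE),
         qdot = outer(vel, dq),
         qddot = outer(acc, dq))
  }
  structure(list(q_start = q_start, q_end = q_end, T = T, eval = eval_fun),
            class = "reference_trajectory")
}

#' PD gains
#'
#' Per-joint proportional (`Kp`, excitation per rad of angle error) and
#' derivative (`Kd`, excitation per rad/s of velocity error) gains of the
#' excitation controller.
#'
#' @param Kp,Kd Non-negative numeric vectors (one entry per joint).
#' @return An object of class `pd_gains`.
#' @export
pd_gains <- function(Kp, Kd) {
  stopifnot(is.numeric(Kp), is.numeric(Kd), length(Kp) == length(Kd),
            all(Kp >= 0), all(Kd >= 0))
  structure(list(Kp = Kp, Kd = Kd), class = "pd_gains")
}

#' PD tracking excitations
#'
#' Maps joint tracking errors to muscle excitations. Per joint, the scalar
#' PD signal is `e = Kp (q_des - q) + Kd (qdot_des - qdot)`, expressed in
#' the joint's flexion convention: if `e * flexion_sign > 0` the flexor
#' receives `min(|e|, 1)` and the extensor 0, mirrored otherwise. At most
#' one muscle per joint is excited at any instant; overlapping *activation*
#' (co-contraction) still emerges downstream from the lag of the
#' excitation-activation cascade.
#'
#' @param q,qdot Current joint angles (rad) and velocities (rad/s).
#' @param ref A [reference_trajectory].
#' @param gains A [pd_gains].
#' @param t Time in s.
#' @param flexion_sign +1/-1 per joint (world direction of flexion).
#' @return Numeric vector of 2 excitations per joint in \[0, 1\],
#'   `(flexor, extensor)` blocks in joint order.
#' @export
pd_excitations <- function(q, qdot, ref, gains, t, flexion_sign = rep(1, length(q))) {
  stopifnot(inherits(ref, "reference_trajectory"), inherits(gains, "pd_gains"),
            length(q) == length(gains$Kp), length(qdot) == length(q))
  des <- ref$eval(t)
  e <- gains$Kp * (des$q[1L, ] - q) + gains$Kd * (des$qdot[1L, ] - qdot)
  ef <- e * flexion_sign                    # positive -> flexor
  out <- numeric(2L * length(q))
  out[seq(1L, by = 2L, length.out = length(q))] <- pmin(pmax(ef, 0), 1)
  out[seq(2L, by = 2L, length.out = length(q))] <- pmin(pmax(-ef, 0), 1)
  out
}

#' Build a PD excitation controller for the simulator
#'
#' @inheritParams pd_excitations
#' @return A function `(t, q, qdot) -> excitations` for [simulate_arm] or
#'   [simulate_joint].
#' @export
pd_controller <- function(ref, gains, flexion_sign) {
  force(ref); force(gains); force(flexion_sign)
  function(t, q, qdot) pd_excitations(q, qdot, ref, gains, t, flexion_sign)
}

#' Analytic inverse activation plan for a single joint
#'
#' For a purely inertial single-joint load tracking a reference exactly,
#' the required torque is `tau(t) = I * qddot_des(t)`. The muscle whose
#' anatomical direction matches `sign(tau)` receives the activation
#' `a(t) = |tau| / (F_max * r * fv_gain(v_norm))`, with the velocity taken
#' from the reference in that muscle's shortening convention; the other
#' muscle stays silent (no co-contraction in the plan). Executing this plan
#' through [simulate_joint] in `mode = "direct"` reproduces the reference
#' kinematics to integration accuracy.
#'
#' @param ref A single-joint [reference_trajectory].
#' @param inertia Load moment of inertia in kg m^2 (> 0).
#' @param muscles List with [fv_params] entries `flexor` and `extensor`.
#' @param flexion_sign +1/-1: world direction of flexion.
#' @param n_samples Number of samples of the returned plan series.
#' @return An object of class `toy_plan`: a list with `eval` (function
#'   `t -> 2-column activation matrix`), `torque` (function of `t`), and a
#'   sampled data frame `series` (`time`, `a_flexor`, `a_extensor`, `tau`).
#' @export
toy_inverse_plan <- function(ref, inertia, muscles, flexion_sign = 1,
                             n_samples = 501) {
  stopifnot(inherits(ref, "reference_trajectory"), length(ref$q_start) == 1L,
            is.numeric(inertia), inertia > 0,
            inherits(muscles$flexor, "fv_params"),
            inherits(muscles$extensor, "fv_params"))
  msign <- c(flexor = flexion_sign, extensor = -flexion_sign)
  plan_at <- function(t) {
    des <- ref$eval(t)
    tau <- inertia * des$qddot[, 1L]
    qd <- des$qdot[, 1L]
    a <- matrix(0, length(t), 2L,
                dimnames = list(NULL, c("flexor", "extensor")))
    for (k in seq_along(t)) {
      if (tau[k] == 0) next
      mi <- if (sign(tau[k]) == sign(msign["flexor"])) 1L else 2L
      p <- muscles[[mi]]
      vn <- normalize_joint_velocity(msign[mi] * qd[k], p)
      g <- .fv_raw(vn, p$d1, p$d2, p$d3)
      if (g <= 0) {
        stop(sprintf(
          "toy_inverse_plan: infeasible plan at t = %.3f s (fv_gain <= 0 at v_norm = %.3f)",
          t[k], vn), call. = FALSE)
      }
      a[k, mi] <- as.numeric(abs(tau[k]) / (p$F_max * p$r * g))
    }
    list(a = a, tau = tau)
  }
  tt <- seq(0, ref$T, length.out = n_samples)
  smp <- plan_at(tt)
  if (max(smp$a) > 1) {
    stop(sprintf(
      "toy_inverse_plan: infeasible plan, peak activation demand %.2f > 1",
      max(smp$a)), call. = FALSE)
  }
  structure(
    list(eval = function(t) plan_at(t)$a,
         torque = function(t) plan_at(t)$tau,
         series = data.frame(time = tt, a_flexor = smp$a[, 1L],
                             a_extensor = smp$a[, 2L], tau = smp$tau),
         ref = ref, inertia = inertia, flexion_sign = flexion_sign),
    class = "toy_plan"
  )
}
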