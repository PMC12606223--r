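# Fast unchecked force-velocity gain used inside integration loops.
.fv_raw <- function(v, d1, d2, d3) {
  ifelse(v > 0,
         (1 - v) / (1 + d1 * v),
         d2 - (d2 - 1) * (1 + v) / (1 - d3 * v))
}

#' Hand-force perturbation
#'
#' A brief external point force applied to the hand, with direction defined
#' relative to the instantaneous hand velocity (recomputed at every
#' integration step). Defaults follow a mild mid-reach shove: 100 N at +90
#' degrees (anticlockwise) to the hand velocity, switched on 0.150 s after
#' movement onset for a 10 ms rectangular pulse.
#'
#' @param magnitude Force magnitude in N (>= 0).
#' @param angle Direction relative to the hand velocity in rad,
#'   anticlockwise positive (default `pi/2`).
#' @param onset Onset time in s.
#' @param duration Pulse duration in s (> 0).
#' @param fallback_direction Unit-normalized world direction used if the
#'   hand is (numerically) at rest during the window, where a
#'   velocity-relative direction is undefined.
#' @return An object of class `perturbation`.
#' @export
perturbation <- function(magnitude = 100, angle = pi / 2, onset = 0.150,
                         duration = 0.010, fallback_direction = c(0, 1)) {
  stopifnot(is.numeric(magnitude), magnitude >= 0,
            is.numeric(angle), is.finite(angle),
            is.numeric(onset), onset >= 0,
            is.numeric(duration), duration > 0,
            length(fallback_direction) == 2L,
            any(fallback_direction != 0))
  structure(list(magnitude = magnitude, angle = angle, onset = onset,
                 duration = duration,
                 fallback_direction =
                   fallback_direction / sqrt(sum(fallback_direction^2))),
            class = "perturbation")
}

#' Evaluate a perturbation force
#'
#' Zero outside `[onset, onset + duration]`; inside the window, a vector of
#' the configured magnitude rotated by `angle` from the unit hand-velocity
#' vector (so the default is orthogonal to the hand path). If the hand
#' speed is below `speed_tol` inside the window the configured fallback
#' direction is used instead and a warning is raised.
#'
#' @param pert A [perturbation].
#' @param t Time in s.
#' @param hand_velocity 2D hand velocity in m/s.
#' @param speed_tol Speed below which the direction is deemed undefined.
#' @return 2D force vector in N.
#' @export
perturbation_force <- function(pert, t, hand_velocity, speed_tol = 1e-9) {
  stopifnot(inherits(pert, "perturbation"), length(hand_velocity) == 2L)
  if (t < pert$onset || t > pert$onset + pert$duration || pert$magnitude == 0) {
    return(c(0, 0))
  }
  sp <- sqrt(sum(hand_velocity^2))
  if (sp < speed_tol) {
    warning("perturbation_force: hand at rest, using fallback direction",
            call. = FALSE)
    u <- pert$fallback_direction
  } else {
    u <- hand_velocity / sp
  }
  ca <- cos(pert$angle); sa <- sin(pert$angle)
  pert$magnitude * c(ca * u[1] - sa * u[2], sa * u[1] + ca * u[2])
}

# --- simulation result container ---------------------------------------------

#' Simulation result container
#'
#' Aligned, uniformly sampled time series from a muscle-driven simulation
#' (or a synthetic fixture). All matrices share the time grid row-wise;
#' joint-indexed matrices have one column per joint, muscle-indexed ones one
#' column per muscle in `muscle_names` order.
#'
#' @param time Time grid in s.
#' @param q,qdot,qddot Joint angles (rad), velocities (rad/s),
#'   accelerations (rad/s^2); n x J matrices.
#' @param excitation,activation Dimensionless, n x 2J.
#' @param torque Signed world-frame torque contribution of each muscle in
#'   N m, n x 2J.
#' @param force_norm Normalized muscle force (activation x FV gain), n x 2J.
#' @param v_norm Normalized muscle shortening velocity, n x 2J.
#' @param torque_net Net muscle torque per joint in N m (world convention),
#'   n x J.
#' @param hand_pos,hand_vel,ext_force Hand position (m), velocity (m/s) and
#'   applied external force (N); n x 2 matrices or NULL.
#' @param joints Character vector of joint names.
#' @param muscle_names Character vector (2 per joint, `<joint>_<role>`).
#' @param muscle_sign Named world-frame torque signs of the muscles.
#' @param muscle_params Named list of [fv_params] per muscle.
#' @param flexion_sign Named +1/-1 per joint.
#' @param meta List of free-form metadata (config snapshot, warnings, ...).
#' @return An object of class `sim_result`.
#' @export
sim_result <- function(time, q, qdot, qddot, excitation, activation, torque,
                       force_norm, v_norm, torque_net,
                       hand_pos = NULL, hand_vel = NULL, ext_force = NULL,
                       joints, muscle_names, muscle_sign, muscle_params,
                       flexion_sign, meta = list()) {
  n <- length(time)
  chk <- function(x, ncol_exp) {
    is.null(x) || (is.matrix(x) && nrow(x) == n && ncol(x) == ncol_exp)
  }
  stopifnot(n >= 1L, !is.unsorted(time),
            chk(q, length(joints)), chk(qdot, length(joints)),
            chk(qddot, length(joints)), chk(torque_net, length(joints)),
            chk(excitation, length(muscle_names)),
            chk(activation, length(muscle_names)),
            chk(torque, length(muscle_names)),
            chk(force_norm, length(muscle_names)),
            chk(v_norm, length(muscle_names)),
            chk(hand_pos, 2L), chk(hand_vel, 2L), chk(ext_force, 2L),
            length(muscle_names) == 2L * length(joints),
            all(activation >= 0), all(activation <= 1))
  colnames(q) <- colnames(qdot) <- colnames(qddot) <-
    colnames(torque_net) <- joints
  if (!is.null(hand_pos)) colnames(hand_pos) <- c("x", "y")
  if (!is.null(hand_vel)) colnames(hand_vel) <- c("x", "y")
  if (!is.null(ext_force)) colnames(ext_force) <- c("x", "y")
  colnames(excitation) <- colnames(activation) <- colnames(torque) <-
    colnames(force_norm) <- colnames(v_norm) <- muscle_names
  structure(
    list(time = time, q = q, qdot = qdot, qddot = qddot,
         excitation = excitation, activation = activation, torque = torque,
         force_norm = force_norm, v_norm = v_norm, torque_net = torque_net,
         hand_pos = hand_pos, hand_vel = hand_vel, ext_force = ext_force,
         joints = joints, muscle_names = muscle_names,
         muscle_sign = muscle_sign, muscle_params = muscle_params,
         flexion_sign = flexion_sign, meta = meta),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d samples over %.3f s; joints: %s\n",
              length(x$time), max(x$time) - min(x$time),
              paste(x$joints, collapse = ", ")))
  if (!is.null(x$meta$scenario)) cat(sprintf("  scenario: %s\n",
                                             x$meta$scenario))
  invisible(x)
}

# --- the coupled muscle + rigid-body integrator ------------------------------

# One full dynamics evaluation; returns derivatives plus recordable info.
.arm_deriv <- function(t, q, qdot, S, model, controller, pert, mp, counters) {
  u <- controller(t, q, qdot)
  u <- pmin(pmax(as.numeric(u), 0), 1)
  a <- S[3L, ]
  vm <- mp$msign * qdot[mp$jidx]            # rad/s, shortening-positive
  vn <- vm * mp$r / mp$vmax
  if (any(abs(vn) > 1)) counters$vnorm_exceeded <- counters$vnorm_exceeded + 1L
  gain <- pmax(.fv_raw(vn, mp$d1, mp$d2, mp$d3), 0)
  tq_mag <- a * mp$Fmax * mp$r * gain
  tq_signed <- mp$msign * tq_mag
  tau <- c(tq_signed[1L] + tq_signed[2L],
           tq_signed[3L] + tq_signed[4L],
           tq_signed[5L] + tq_signed[6L])
  hk <- hand_kinematics(model, list(q = q, qdot = qdot))
  fext <- c(0, 0)
  if (!is.null(pert) && t >= pert$onset && t <= pert$onset + pert$duration &&
      pert$magnitude > 0) {
    sp <- sqrt(sum(hk$velocity^2))
    if (sp < 1e-9) {
      counters$pert_fallback <- counters$pert_fallback + 1L
      uv <- pert$fallback_direction
    } else {
      uv <- hk$velocity / sp
    }
    ca <- cos(pert$angle); sa <- sin(pert$angle)
    fext <- pert$magnitude * c(ca * uv[1] - sa * uv[2],
                               sa * uv[1] + ca * uv[2])
  }
  M <- mass_matrix(model, q)
  C <- coriolis_matrix(model, q, qdot)
  gen <- tau - as.numeric(C %*% qdot)
  if (any(fext != 0)) gen <- gen + as.numeric(crossprod(hk$jacobian, fext))
  qddot <- as.numeric(solve(M, gen))
  dS <- activation_rhs(S, u, model$act_tau)
  list(dq = qdot, dqdot = qddot, dS = dS,
       u = u, a = a, tq = tq_signed, fn = a * gain, vn = vn, tau = tau,
       hand_pos = hk$position, hand_vel = hk$velocity, fext = fext,
       qddot = qddot)
}

#' Simulate the muscle-driven arm
#'
#' Fixed-step RK4 integration of the coupled third-order activation
#' dynamics and rigid-body dynamics. The controller supplies muscle
#' excitations continuously (evaluated at every integrator stage), the
#' excitation-activation cascade filters them, Hill-type force-velocity
#' scaling converts activations to torques, and the multibody equations of
#' motion advance the arm. Fully deterministic for a given configuration.
#'
#' A warning summarises any steps at which a muscle's normalized speed
#' exceeded 1 (beyond the Hill model's calibrated range) and any
#' perturbation steps that fell back to a fixed direction.
#'
#' @param model An [arm_model].
#' @param controller Function `(t, q, qdot) -> 6 excitations` in
#'   `model$muscle_names` order; values are clipped to \[0, 1\].
#' @param duration Simulated time in s (>= `dt`).
#' @param dt Integration step in s (default 1e-4).
#' @param pert Optional [perturbation].
#' @param init Initial [arm_state].
#' @param initial_activation Optional 3 x 6 matrix of initial cascade
#'   stages (default all zero).
#' @return A [sim_result] sampled at every integration step.
#' @export
simulate_arm <- function(model, controller, duration, dt = 1e-4,
                         pert = NULL, init = arm_state(c(0, 0, 0)),
                         initial_activation = NULL) {
  stopifnot(inherits(model, "arm_model"), is.function(controller),
            is.numeric(dt), dt > 0, is.numeric(duration), duration >= dt,
            is.null(pert) || inherits(pert, "perturbation"))
  nm <- model$muscle_names
  mp <- list(
    jidx = rep(1:3, each = 2L),
    msign = unname(model$muscle_sign[nm]),
    r = vapply(model$muscles, `[[`, numeric(1), "r"),
    vmax = vapply(model$muscles, `[[`, numeric(1), "v_max"),
    Fmax = vapply(model$muscles, `[[`, numeric(1), "F_max"),
    d1 = vapply(model$muscles, `[[`, numeric(1), "d1"),
    d2 = vapply(model$muscles, `[[`, numeric(1), "d2"),
    d3 = vapply(model$muscles, `[[`, numeric(1), "d3")
  )
  counters <- new.env(parent = emptyenv())
  counters$vnorm_exceeded <- 0L
  counters$pert_fallback <- 0L

  nstep <- max(1L, round(duration / dt))
  n <- nstep + 1L
  time <- seq(0, by = dt, length.out = n)
  q <- matrix(NA_real_, n, 3L); qd <- q; qdd <- q; tnet <- q
  ex <- matrix(NA_real_, n, 6L); ac <- ex; tqm <- ex; fn <- ex; vn <- ex
  hp <- matrix(NA_real_, n, 2L); hv <- hp; fe <- hp

  cq <- init$q; cqd <- init$qdot
  S <- if (is.null(initial_activation)) matrix(0, 3L, 6L) else initial_activation
  rec <- function(i, d, qq, qqd, SS) {
    q[i, ] <<- qq; qd[i, ] <<- qqd; qdd[i, ] <<- d$qddot
    tnet[i, ] <<- d$tau
    ex[i, ] <<- d$u; ac[i, ] <<- SS[3L, ]; tqm[i, ] <<- d$tq
    fn[i, ] <<- d$fn; vn[i, ] <<- d$vn
    hp[i, ] <<- d$hand_pos; hv[i, ] <<- d$hand_vel; fe[i, ] <<- d$fext
  }
  for (s in seq_len(nstep)) {
    t0 <- time[s]
    k1 <- .arm_deriv(t0, cq, cqd, S, model, controller, pert, mp, counters)
    rec(s, k1, cq, cqd, S)
    h <- dt
    k2 <- .arm_deriv(t0 + h / 2, cq + h / 2 * k1$dq, cqd + h / 2 * k1$dqdot,
                     S + h / 2 * k1$dS, model, controller, pert, mp, counters)
    k3 <- .arm_deriv(t0 + h / 2, cq + h / 2 * k2$dq, cqd + h / 2 * k2$dqdot,
                     S + h / 2 * k2$dS, model, controller, pert, mp, counters)
    k4 <- .arm_deriv(t0 + h, cq + h * k3$dq, cqd + h * k3$dqdot,
                     S + h * k3$dS, model, controller, pert, mp, counters)
    cq <- cq + h / 6 * (k1$dq + 2 * k2$dq + 2 * k3$dq + k4$dq)
    cqd <- cqd + h / 6 * (k1$dqdot + 2 * k2$dqdot + 2 * k3$dqdot + k4$dqdot)
    S <- S + h / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
    S <- pmin(pmax(S, 0), 1)
    if (any(!is.finite(cq)) || any(!is.finite(cqd))) {
      stop(sprintf("simulate_arm: simulation diverged at step %d (t = %.4f s)",
                   s, t0 + dt), call. = FALSE)
    }
  }
  kf <- .arm_deriv(time[n], cq, cqd, S, model, controller, pert, mp, counters)
  rec(n, kf, cq, cqd, S)

  if (counters$vnorm_exceeded > 0L) {
    warning(sprintf(
      "simulate_arm: |v_norm| > 1 in %d dynamics evaluations (beyond Hill-model range)",
      counters$vnorm_exceeded), call. = FALSE)
  }
  if (counters$pert_fallback > 0L) {
    warning("simulate_arm: perturbation direction fell back to fixed direction",
            call. = FALSE)
  }
  sim_result(
    time = time, q = q, qdot = qd, qddot = qdd,
    excitation = ex, activation = ac, torque = tqm, force_norm = fn,
    v_norm = vn, torque_net = tnet,
    hand_pos = hp, hand_vel = hv, ext_force = fe,
    joints = model$joints, muscle_names = nm,
    muscle_sign = model$muscle_sign, muscle_params = model$muscles,
    flexion_sign = model$flexion_sign,
    meta = list(dt = dt, duration = duration,
                vnorm_exceeded_evals = counters$vnorm_exceeded,
                perturbation = if (!is.null(pert)) unclass(pert),
                model_lengths = model$lengths,
                model_anchor = model$anchor)
  )
}

#' Simulate a single muscle-driven joint
#'
#' Reduced single-hinge plant `I qddot = tau_muscles` driven by one
#' antagonistic pair, used by the single-joint toy examples. In
#' `mode = "filter"` the controller output is an excitation passed through
#' the activation cascade; in `mode = "direct"` it is applied as the
#' activation itself (used to execute an analytic activation plan exactly).
#'
#' @param inertia Load + limb moment of inertia about the hinge (kg m^2).
#' @param muscles List with [fv_params] entries `flexor` and `extensor`.
#' @param controller Function `(t, q, qdot) -> c(flexor, extensor)`
#'   excitations (or activations in direct mode), clipped to \[0, 1\].
#' @param duration,dt Simulated time and step in s.
#' @param q0,qdot0 Initial angle (rad) and velocity (rad/s).
#' @param flexion_sign +1 or -1: which rotation direction is flexion.
#' @param mode `"filter"` or `"direct"` (see above).
#' @param act_tau Activation stage time constant in s.
#' @param joint_name Name used for the joint in the result.
#' @return A [sim_result] with one joint and two muscles.
#' @export
simulate_joint <- function(inertia, muscles, controller, duration, dt = 1e-4,
                           q0 = 0, qdot0 = 0, flexion_sign = 1,
                           mode = c("filter", "direct"), act_tau = 0.02,
                           joint_name = "joint") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(inertia), inertia > 0,
            inherits(muscles$flexor, "fv_params"),
            inherits(muscles$extensor, "fv_params"),
            is.function(controller), dt > 0, duration >= dt,
            abs(flexion_sign) == 1)
  nm <- paste(joint_name, c("flexor", "extensor"), sep = "_")
  msign <- c(flexion_sign, -flexion_sign); names(msign) <- nm
  prm <- list(muscles$flexor, muscles$extensor); names(prm) <- nm
  r2 <- vapply(prm, `[[`, numeric(1), "r")
  vmax2 <- vapply(prm, `[[`, numeric(1), "v_max")
  Fmax2 <- vapply(prm, `[[`, numeric(1), "F_max")
  d1 <- vapply(prm, `[[`, numeric(1), "d1")
  d2 <- vapply(prm, `[[`, numeric(1), "d2")
  d3 <- vapply(prm, `[[`, numeric(1), "d3")

  deriv <- function(t, q, qdot, S) {
    u <- pmin(pmax(as.numeric(controller(t, q, qdot)), 0), 1)
    a <- if (mode == "direct") u else S[3L, ]
    vnorm <- msign * qdot * r2 / vmax2
    gain <- pmax(.fv_raw(vnorm, d1, d2, d3), 0)
    tq <- msign * a * Fmax2 * r2 * gain
    list(dq = qdot, dqdot = sum(tq) / inertia,
         dS = if (mode == "direct") NULL else activation_rhs(S, u, act_tau),
         u = u, a = a, tq = tq, fn = a * gain, vn = vnorm, tau = sum(tq))
  }
  nstep <- max(1L, round(duration / dt)); n <- nstep + 1L
  time <- seq(0, by = dt, length.out = n)
  q <- matrix(NA_real_, n, 1L); qd <- q; qdd <- q; tnet <- q
  ex <- matrix(NA_real_, n, 2L); ac <- ex; tqm <- ex; fn <- ex; vn <- ex
  cq <- q0; cqd <- qdot0; S <- matrix(0, 3L, 2L)
  rec <- function(i, d, qq, qqd) {
    q[i, ] <<- qq; qd[i, ] <<- qqd; qdd[i, ] <<- d$dqdot; tnet[i, ] <<- d$tau
    ex[i, ] <<- d$u; ac[i, ] <<- d$a; tqm[i, ] <<- d$tq
    fn[i, ] <<- d$fn; vn[i, ] <<- d$vn
  }
  for (s in seq_len(nstep)) {
    t0 <- time[s]; h <- dt
    k1 <- deriv(t0, cq, cqd, S); rec(s, k1, cq, cqd)
    adv <- function(f, k) if (is.null(k$dS)) S else S + f * k$dS
    k2 <- deriv(t0 + h / 2, cq + h / 2 * k1$dq, cqd + h / 2 * k1$dqdot,
                adv(h / 2, k1))
    k3 <- deriv(t0 + h / 2, cq + h / 2 * k2$dq, cqd + h / 2 * k2$dqdot,
                adv(h / 2, k2))
    k4 <- deriv(t0 + h, cq + h * k3$dq, cqd + h * k3$dqdot, adv(h, k3))
    cq <- cq + h / 6 * (k1$dq + 2 * k2$dq + 2 * k3$dq + k4$dq)
    cqd <- cqd + h / 6 * (k1$dqdot + 2 * k2$dqdot + 2 * k3$dqdot + k4$dqdot)
    if (!is.null(k1$dS)) {
      S <- S + h / 6 * (k1$dS + 2 * k2$dS + 2 * k3$dS + k4$dS)
      S <- pmin(pmax(S, 0), 1)
    }
    if (!is.finite(cq) || !is.finite(cqd)) {
      stop(sprintf("simulate_joint: simulation diverged at step %d", s),
           call. = FALSE)
    }
  }
  kf <- deriv(time[n], cq, cqd, S); rec(n, kf, cq, cqd)
  fs <- flexion_sign; names(fs) <- joint_name
  sim_result(
    time = time, q = q, qdot = qd, qddot = qdd,
    excitation = ex, activation = ac, torque = tqm, force_norm = fn,
    v_norm = vn, torque_net = tnet,
    joints = joint_name, muscle_names = nm, muscle_sign = msign,
    muscle_params = prm, flexion_sign = fs,
    meta = list(dt = dt, duration = duration, inertia = inertia, mode = mode)
  )
}
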