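#' Planar three-link arm model
#'
#' Anthropometry and actuation of a horizontal-plane (gravity-free) arm with
#' hinge joints at the shoulder, elbow and wrist, each driven by one
#' antagonistic pair of monoarticular Hill-type muscles acting through
#' constant moment arms.
#'
#' Coordinate convention: world frame with +x to the subject's right and
#' +y to the front (a right arm seen from above), anticlockwise rotations
#' positive, shoulder anchored at `anchor`. Joint angles `q` are measured
#' relative to the parent segment's axis (the shoulder angle relative to the
#' world x axis), so distal segments inherit proximal rotation - the source
#' of the centrifugal/Coriolis/Euler interaction torques between joints.
#' `flexion_sign` states which rotation direction is anatomical flexion at
#' each joint (+1 = anticlockwise); the flexor of a pair produces torque in
#' that direction, the extensor in the opposite one.
#'
#' @param lengths Segment lengths in m (upper arm, forearm, hand).
#' @param masses Segment masses in kg.
#' @param com Centre-of-mass offsets from the proximal joint in m
#'   (default mid-segment).
#' @param inertia Segment moments of inertia about the centre of mass in
#'   kg m^2 (default slender-rod values `m * L^2 / 12`).
#' @param anchor Shoulder position in the world frame (m).
#' @param flexion_sign Named numeric (+1/-1) per joint.
#' @param muscles Named list of six [fv_params], keys
#'   `<joint>_<flexor|extensor>`.
#' @param act_tau Activation-cascade stage time constant in s.
#' @param joint_limits Optional 3 x 2 matrix of angle limits in rad
#'   (unused by the dynamics; off by default).
#' @return An object of class `arm_model`.
#' @export
arm_model <- function(lengths = c(0.30, 0.30, 0.15),
                      masses = c(2.0, 1.5, 0.5),
                      com = lengths / 2,
                      inertia = masses * lengths^2 / 12,
                      anchor = c(0, 0),
                      flexion_sign = c(shoulder = 1, elbow = 1, wrist = 1),
                      muscles = default_arm_muscles(),
                      act_tau = 0.02,
                      joint_limits = NULL) {
  joints <- c("shoulder", "elbow", "wrist")
  stopifnot(length(lengths) == 3L, all(lengths > 0),
            length(masses) == 3L, all(masses > 0),
            length(com) == 3L, all(com > 0), all(com <= lengths),
            length(inertia) == 3L, all(inertia > 0),
            length(anchor) == 2L, all(is.finite(anchor)),
            length(flexion_sign) == 3L, all(abs(flexion_sign) == 1),
            is.numeric(act_tau), act_tau > 0)
  names(flexion_sign) <- joints
  muscle_names <- as.vector(t(outer(joints, c("flexor", "extensor"),
                                    paste, sep = "_")))
  stopifnot(setequal(names(muscles), muscle_names),
            all(vapply(muscles, inherits, logical(1), "fv_params")))
  muscles <- muscles[muscle_names]
  # world-frame torque sign of each muscle: flexor acts in flexion direction
  muscle_sign <- rep(flexion_sign, each = 2L) * rep(c(1, -1), times = 3L)
  names(muscle_sign) <- muscle_names
  # configuration-independent rotational part of the mass matrix:
  # entry (j, k) collects the inertias of all links distal to both joints
  ipart <- outer(1:3, 1:3, function(j, k) {
    mx <- pmax(j, k)
    vapply(mx, function(i) sum(inertia[i:3]), numeric(1))
  })
  structure(
    list(joints = joints, lengths = lengths, masses = masses, com = com,
         inertia = inertia, anchor = anchor, flexion_sign = flexion_sign,
         muscles = muscles, muscle_names = muscle_names,
         muscle_sign = muscle_sign, act_tau = act_tau,
         joint_limits = joint_limits, .ipart = ipart),
    class = "arm_model"
  )
}

#' Default muscle parameter set for the reaching arm
#'
#' Plausible human-scale strengths with identical flexor/extensor pairs
#' (so the strength-ratio weight `b` is 1 at each joint) and a common
#' maximum joint velocity of 20 rad/s.
#'
#' @return Named list of six [fv_params].
#' @export
default_arm_muscles <- function() {
  sh <- fv_params(v_max = 1.0, r = 0.05, F_max = 600)
  el <- fv_params(v_max = 1.0, r = 0.05, F_max = 400)
  wr <- fv_params(v_max = 0.6, r = 0.03, F_max = 150)
  list(shoulder_flexor = sh, shoulder_extensor = sh,
       elbow_flexor = el, elbow_extensor = el,
       wrist_flexor = wr, wrist_extensor = wr)
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> planar 3-link arm\n")
  cat(sprintf("  segments: L = %s m, m = %s kg\n",
              paste(x$lengths, collapse = "/"),
              paste(x$masses, collapse = "/")))
  cat(sprintf("  muscles: %s\n", paste(x$muscle_names, collapse = ", ")))
  invisible(x)
}

#' Arm state
#'
#' @param q Three joint angles in rad (relative to the parent segment),
#'   unwrapped (no modular arithmetic).
#' @param qdot Three joint angular velocities in rad/s.
#' @param t Time stamp in s.
#' @return An object of class `arm_state`.
#' @export
arm_state <- function(q, qdot = c(0, 0, 0), t = 0) {
  stopifnot(is.numeric(q), length(q) == 3L, all(is.finite(q)),
            is.numeric(qdot), length(qdot) == 3L, all(is.finite(qdot)),
            is.numeric(t), length(t) == 1L, is.finite(t))
  structure(list(q = as.numeric(q), qdot = as.numeric(qdot), t = t),
            class = "arm_state")
}

# Centre-of-mass Jacobians (list of 2 x 3) and hand Jacobian for angles q.
.com_jacobians <- function(model, q) {
  th <- cumsum(q)
  ct <- cos(th); st <- sin(th)
  L <- model$lengths; lc <- model$com
  Js <- vector("list", 3L)
  for (i in 1:3) {
    J <- matrix(0, 2L, 3L)
    for (j in seq_len(i)) {
      sx <- 0; sy <- 0
      if (i > j) {
        idx <- j:(i - 1L)
        sx <- sum(-L[idx] * st[idx]); sy <- sum(L[idx] * ct[idx])
      }
      J[1L, j] <- sx - lc[i] * st[i]
      J[2L, j] <- sy + lc[i] * ct[i]
    }
    Js[[i]] <- J
  }
  Js
}

# Partial derivative of the i-th COM Jacobian w.r.t. q_m.
.com_jacobian_partial <- function(model, q, i, m) {
  th <- cumsum(q)
  ct <- cos(th); st <- sin(th)
  L <- model$lengths; lc <- model$com
  dJ <- matrix(0, 2L, 3L)
  if (m > i) return(dJ)
  for (j in seq_len(i)) {
    lo <- max(j, m)
    sx <- 0; sy <- 0
    if (i > lo) {
      idx <- lo:(i - 1L)
      sx <- sum(-L[idx] * ct[idx]); sy <- sum(-L[idx] * st[idx])
    }
    dJ[1L, j] <- sx - lc[i] * ct[i]
    dJ[2L, j] <- sy - lc[i] * st[i]
  }
  dJ
}

#' Configuration-dependent mass matrix
#'
#' Symmetric positive-definite 3 x 3 inertia matrix `M(q)` of the chain,
#' assembled from the centre-of-mass Jacobians:
#' `M = sum_i m_i J_i' J_i + (rotational inertia part)`.
#'
#' @param model An [arm_model].
#' @param q Joint angles in rad.
#' @return 3 x 3 numeric matrix.
#' @export
mass_matrix <- function(model, q) {
  stopifnot(inherits(model, "arm_model"), length(q) == 3L)
  Js <- .com_jacobians(model, q)
  M <- model$.ipart
  for (i in 1:3) M <- M + model$masses[i] * crossprod(Js[[i]])
  M
}

# dM/dq_m for m = 1..3, returned as a list of 3 x 3 matrices.
.mass_matrix_partials <- function(model, q) {
  Js <- .com_jacobians(model, q)
  lapply(1:3, function(m) {
    dM <- matrix(0, 3L, 3L)
    for (i in 1:3) {
      if (m > i) next
      dJ <- .com_jacobian_partial(model, q, i, m)
      A <- crossprod(dJ, Js[[i]])
      dM <- dM + model$masses[i] * (A + t(A))
    }
    dM
  })
}

#' Coriolis/centrifugal matrix
#'
#' Velocity-product matrix `C(q, qdot)` built from the Christoffel symbols
#' of the mass matrix, so that the equations of motion read
#' `M(q) qddot + C(q, qdot) qdot = tau` and `dM/dt - 2C` is skew-symmetric.
#'
#' @inheritParams mass_matrix
#' @param qdot Joint angular velocities in rad/s.
#' @return 3 x 3 numeric matrix.
#' @export
coriolis_matrix <- function(model, q, qdot) {
  stopifnot(inherits(model, "arm_model"), length(q) == 3L, length(qdot) == 3L)
  dM <- .mass_matrix_partials(model, q)
  C <- matrix(0, 3L, 3L)
  for (k in 1:3) for (j in 1:3) {
    s <- 0
    for (i in 1:3) {
      s <- s + (dM[[i]][k, j] + dM[[j]][k, i] - dM[[k]][i, j]) * qdot[i]
    }
    C[k, j] <- s / 2
  }
  C
}

#' Hand kinematics
#'
#' Forward kinematics of the fingertip (tip of the hand segment): position,
#' velocity and the 2 x 3 Jacobian mapping joint velocities to hand
#' velocity (also used to map an external hand force to joint torques via
#' its transpose).
#'
#' @param model An [arm_model].
#' @param state An [arm_state] (or a list with `q` and `qdot`).
#' @return List with `position` (m), `velocity` (m/s) and `jacobian`.
#' @export
hand_kinematics <- function(model, state) {
  stopifnot(inherits(model, "arm_model"))
  q <- state$q; qdot <- state$qdot
  th <- cumsum(q)
  ct <- cos(th); st <- sin(th)
  L <- model$lengths
  pos <- model$anchor + c(sum(L * ct), sum(L * st))
  J <- matrix(0, 2L, 3L)
  for (j in 1:3) {
    idx <- j:3
    J[1L, j] <- sum(-L[idx] * st[idx])
    J[2L, j] <- sum(L[idx] * ct[idx])
  }
  list(position = pos, velocity = as.numeric(J %*% qdot), jacobian = J)
}

#' Forward dynamics of the arm
#'
#' Solves `M(q) qddot + C(q, qdot) qdot = tau + J' F_ext` for the joint
#' angular accelerations. The plane is horizontal, so there is no gravity
#' term; all velocity-product (interaction) torques are carried by `C`.
#'
#' @param model An [arm_model].
#' @param state An [arm_state].
#' @param joint_torques Net muscle torques in N m (3, world convention).
#' @param external_force External 2D force in N applied at the hand point.
#' @return Joint angular accelerations in rad/s^2 (3).
#' @examples
#' m <- arm_model()
#' forward_dynamics(m, arm_state(c(0.5, 1, 0)), c(0, 0, 0))  # equilibrium
#' @export
forward_dynamics <- function(model, state, joint_torques,
                             external_force = c(0, 0)) {
  stopifnot(inherits(model, "arm_model"), length(joint_torques) == 3L,
            length(external_force) == 2L)
  q <- state$q; qdot <- state$qdot
  M <- mass_matrix(model, q)
  C <- coriolis_matrix(model, q, qdot)
  tau <- as.numeric(joint_torques)
  if (any(external_force != 0)) {
    J <- hand_kinematics(model, state)$jacobian
    tau <- tau + as.numeric(crossprod(J, external_force))
  }
  as.numeric(solve(M, tau - C %*% qdot))
}

#' Total kinetic energy of the arm
#'
#' `0.5 * qdot' M(q) qdot`; the horizontal plane has no potential energy,
#' so this is the conserved total energy of a passive, unforced arm.
#'
#' @inheritParams forward_dynamics
#' @return Kinetic energy in J.
#' @export
kinetic_energy <- function(model, state) {
  as.numeric(crossprod(state$qdot, mass_matrix(model, state$q) %*%
                         state$qdot)) / 2
}

#' Angular momentum about the shoulder anchor
#'
#' Conserved when no muscle torques and no external forces act.
#'
#' @inheritParams forward_dynamics
#' @return Angular momentum in kg m^2/s.
#' @export
angular_momentum <- function(model, state) {
  q <- state$q; qdot <- state$qdot
  th <- cumsum(q); thdot <- cumsum(qdot)
  ct <- cos(th); st <- sin(th)
  L <- model$lengths; lc <- model$com
  Js <- .com_jacobians(model, q)
  H <- 0
  px <- 0; py <- 0  # proximal joint position relative to the anchor
  for (i in 1:3) {
    pc <- c(px + lc[i] * ct[i], py + lc[i] * st[i])
    vc <- as.numeric(Js[[i]] %*% qdot)
    H <- H + model$masses[i] * (pc[1] * vc[2] - pc[2] * vc[1]) +
      model$inertia[i] * thdot[i]
    px <- px + L[i] * ct[i]; py <- py + L[i] * st[i]
  }
  H
}
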