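#' Load a scenario configuration
#'
#' Resolves a named packaged scenario (`"toy"`, `"forward"`, `"sideways"`,
#' `"cross_body"`, `"forward_perturbed"`) or a YAML file path to a complete,
#' validated configuration list. Every parameter has an explicit value in
#' the committed YAML files; `overrides` are merged recursively on top.
#'
#' @param name Scenario name or path to a YAML config file.
#' @param overrides Nested list of values to override.
#' @return A validated configuration list of class `scenario_config`.
#' @export
scenario_config <- function(name, overrides = list()) {
  known <- c("toy", "forward", "sideways", "cross_body", "forward_perturbed")
  path <- if (file.exists(name) && grepl("\\.ya?ml$", name)) {
    name
  } else if (name %in% known) {
    system.file("configs", paste0(name, ".yaml"), package = "jointfv",
                mustWork = TRUE)
  } else {
    stop(sprintf("scenario_config: unknown scenario '%s'; valid names: %s",
                 name, paste(known, collapse = ", ")), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  merge_rec <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge_rec(base[[k]], upd[[k]])
      } else {
        upd[[k]]
      }
    }
    base
  }
  cfg <- merge_rec(cfg, overrides)
  validate_config(cfg)
  class(cfg) <- c("scenario_config", "list")
  cfg
}

#' Validate a scenario configuration
#'
#' Checks structural completeness and value ranges; stops with a
#' diagnostic naming the offending field.
#'
#' @param cfg Configuration list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  req <- function(ok, what) {
    if (!isTRUE(ok)) stop(sprintf("invalid config: %s", what), call. = FALSE)
  }
  req(is.character(cfg$scenario), "`scenario` must be a string")
  req(cfg$kind %in% c("reach", "toy"), "`kind` must be 'reach' or 'toy'")
  req(is.numeric(cfg$duration) && cfg$duration > 0, "`duration` must be > 0")
  req(is.numeric(cfg$dt) && cfg$dt > 0 && cfg$dt <= cfg$duration,
      "`dt` must be in (0, duration]")
  if (cfg$kind == "reach") {
    r <- cfg$reach
    req(is.list(r), "`reach` block missing")
    req(is.numeric(r$T) && r$T > 0, "`reach$T` must be > 0")
    req(length(r$target) == 2L, "`reach$target` must be a 2-vector (m)")
    req(length(r$initial_posture_deg) == 3L,
        "`reach$initial_posture_deg` must have 3 entries")
    req(is.numeric(r$wrist_final), "`reach$wrist_final` must be numeric (rad)")
    req(is.numeric(r$target_tolerance) && r$target_tolerance > 0,
        "`reach$target_tolerance` must be > 0")
    req(length(cfg$gains$Kp) == 3L && length(cfg$gains$Kd) == 3L,
        "`gains$Kp`/`gains$Kd` must have 3 entries")
    req(is.list(cfg$model$muscles) &&
          all(c("shoulder", "elbow", "wrist") %in% names(cfg$model$muscles)),
        "`model$muscles` must define shoulder, elbow, wrist")
    if (!is.null(cfg$perturbation)) {
      p <- cfg$perturbation
      req(is.numeric(p$magnitude) && p$magnitude >= 0,
          "`perturbation$magnitude` must be >= 0")
      req(is.numeric(p$duration) && p$duration > 0,
          "`perturbation$duration` must be > 0")
    }
  } else {
    t <- cfg$toy
    req(is.list(t), "`toy` block missing")
    req(is.numeric(t$excursion), "`toy$excursion` must be numeric (rad)")
    req(is.numeric(t$T) && t$T > 0, "`toy$T` must be > 0")
    req(is.numeric(t$inertia) && t$inertia > 0, "`toy$inertia` must be > 0")
    req(is.list(t$muscle), "`toy$muscle` block missing")
    req(is.numeric(t$gains$Kp) && is.numeric(t$gains$Kd),
        "`toy$gains` must give Kp and Kd")
  }
  invisible(cfg)
}

.fv_params_from_cfg <- function(m) {
  fv_params(d1 = m$d1 %||% 4, d2 = m$d2 %||% 1.8, d3 = m$d3 %||% 30.24,
            v_max = m$v_max, r = m$r, F_max = m$F_max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an [arm_model] from a configuration's `model` block
#'
#' @param mcfg The `model` sub-list of a reach [scenario_config].
#' @return An [arm_model].
#' @export
build_arm_model <- function(mcfg) {
  pairs <- lapply(mcfg$muscles, .fv_params_from_cfg)
  muscles <- list(
    shoulder_flexor = pairs$shoulder, shoulder_extensor = pairs$shoulder,
    elbow_flexor = pairs$elbow, elbow_extensor = pairs$elbow,
    wrist_flexor = pairs$wrist, wrist_extensor = pairs$wrist)
  arm_model(
    lengths = as.numeric(mcfg$lengths %||% c(0.30, 0.30, 0.15)),
    masses = as.numeric(mcfg$masses %||% c(2.0, 1.5, 0.5)),
    muscles = muscles,
    act_tau = mcfg$act_tau %||% 0.02
  )
}

#' Inverse kinematics for a reach target
#'
#' Closed-form planar inverse kinematics: the wrist angle is prescribed
#' (configured final wrist posture), so the forearm + hand act as one
#' pseudo-link from the elbow to the fingertip and the remaining two
#' unknowns follow from the standard two-link solution. The elbow branch
#' (bend direction) is chosen to match the initial posture.
#'
#' @param model An [arm_model].
#' @param target 2D target position in m (world frame).
#' @param wrist_final Final wrist angle in rad.
#' @param q0 Initial joint angles in rad (branch selection only).
#' @return Final joint angles `c(q1, q2, q3)` in rad.
#' @export
reach_ik <- function(model, target, wrist_final, q0) {
  L <- model$lengths
  le <- sqrt(L[2]^2 + L[3]^2 + 2 * L[2] * L[3] * cos(wrist_final))
  phi <- atan2(L[3] * sin(wrist_final), L[2] + L[3] * cos(wrist_final))
  d <- target - model$anchor
  dd <- sum(d^2)
  c2 <- (dd - L[1]^2 - le^2) / (2 * L[1] * le)
  if (abs(c2) > 1) {
    stop(sprintf("reach_ik: target (%.2f, %.2f) unreachable", target[1],
                 target[2]), call. = FALSE)
  }
  branch <- if ((q0[2] + phi) < 0) -1 else 1
  alpha <- branch * acos(c2)
  q2 <- alpha - phi
  q1 <- atan2(d[2], d[1]) - atan2(le * sin(alpha), L[1] + le * cos(alpha))
  c(q1, q2, wrist_final)
}

#' Run a packaged scenario
#'
#' Executes one of the committed experiment conditions: the single-joint
#' toy movement, or a reach (forward, sideways-ipsilateral, cross-body,
#' or forward with a hand-force perturbation). Reach results carry
#' `meta$reach_time`, the first time the hand enters the target tolerance
#' and stays inside it for the remainder of the run (NA if never).
#'
#' @param config A [scenario_config], or a scenario name passed through
#'   [scenario_config].
#' @param overrides Optional overrides if `config` is a name.
#' @return For reaches, a [sim_result]. For the toy scenario, a list of
#'   class `toy_result` with time-aligned elements `plan` (analytic
#'   inverse-dynamics execution) and `tracked` (PD-controlled execution),
#'   plus the `plan_spec` ([toy_inverse_plan] object).
#' @export
run_scenario <- function(config, overrides = list()) {
  if (is.character(config)) config <- scenario_config(config, overrides)
  stopifnot(inherits(config, "scenario_config"))
  if (config$kind == "toy") .run_toy(config) else .run_reach(config)
}

.run_reach <- function(cfg) {
  model <- build_arm_model(cfg$model)
  q0 <- as.numeric(cfg$reach$initial_posture_deg) * pi / 180
  qf <- reach_ik(model, as.numeric(cfg$reach$target), cfg$reach$wrist_final,
                 q0)
  ref <- minimum_jerk_reference(q0, qf, cfg$reach$T)
  gains <- pd_gains(as.numeric(cfg$gains$Kp), as.numeric(cfg$gains$Kd))
  ctrl <- pd_controller(ref, gains, model$flexion_sign)
  pert <- NULL
  if (!is.null(cfg$perturbation)) {
    p <- cfg$perturbation
    pert <- perturbation(magnitude = p$magnitude,
                         angle = (p$angle_deg %||% 90) * pi / 180,
                         onset = p$onset %||% 0.150,
                         duration = p$duration %||% 0.010)
  }
  res <- simulate_arm(model, ctrl, duration = cfg$duration, dt = cfg$dt,
                      pert = pert, init = arm_state(q0))
  target <- as.numeric(cfg$reach$target)
  d <- sqrt((res$hand_pos[, 1L] - target[1L])^2 +
              (res$hand_pos[, 2L] - target[2L])^2)
  inside <- d < cfg$reach$target_tolerance
  stays <- rev(cumprod(rev(inside))) > 0
  res$meta$scenario <- cfg$scenario
  res$meta$config <- unclass(cfg)
  res$meta$target <- target
  res$meta$q_final_ref <- qf
  res$meta$hand_target_distance <- d
  res$meta$reach_time <- if (any(stays)) res$time[which(stays)[1L]] else NA_real_
  res
}

.run_toy <- function(cfg) {
  t <- cfg$toy
  p <- .fv_params_from_cfg(t$muscle)
  muscles <- list(flexor = p, extensor = p)
  ref <- minimum_jerk_reference(0, t$excursion, t$T)
  plan <- toy_inverse_plan(ref, t$inertia, muscles)
  plan_ctrl <- function(tt, q, qdot) plan$eval(tt)[1L, ]
  res_plan <- simulate_joint(t$inertia, muscles, plan_ctrl,
                             duration = cfg$duration, dt = cfg$dt,
                             mode = "direct")
  gains <- pd_gains(t$gains$Kp, t$gains$Kd)
  pd <- pd_controller(ref, gains, flexion_sign = 1)
  res_pd <- simulate_joint(t$inertia, muscles, pd, duration = cfg$duration,
                           dt = cfg$dt, mode = "filter",
                           act_tau = t$act_tau %||% 0.02)
  res_plan$meta$scenario <- "toy (analytic plan)"
  res_pd$meta$scenario <- "toy (PD-tracked)"
  res_plan$meta$config <- res_pd$meta$config <- unclass(cfg)
  structure(list(plan = res_plan, tracked = res_pd, plan_spec = plan),
            class = "toy_result")
}

#' Generate a synthetic single-joint fixture
#'
#' Deterministic synthetic simulation results emulating the shapes seen in
#' muscle-driven reaches (smooth bell-shaped joint velocities, tri-phasic
#' activation bursts), for testing the analysis and plotting layers without
#' running the dynamics engine. Torques are produced through the package's
#' own muscle model, so fixture trajectories obey the joint-fv relations
#' by construction. Kinds:
#' \describe{
#'   \item{single_muscle}{Constant flexor activation, silent extensor,
#'     bell-shaped shortening velocity: the joint-FV trajectory lies
#'     exactly on the activation-scaled flexor FV curve.}
#'   \item{coactivated}{Equal constant activations and a symmetric velocity
#'     sweep: the trajectory is odd-symmetric about the origin.}
#'   \item{biphasic_reach}{A primary and a smaller homing-in velocity hump
#'     with tri-phasic (agonist-antagonist-agonist) activation bursts,
#'     optionally with seeded activation noise.}
#' }
#'
#' @param kind Fixture kind (see above).
#' @param n_steps Number of samples (>= 3).
#' @param seed Integer seed used when `noise > 0` (deterministic for a
#'   given seed).
#' @param noise Standard deviation of Gaussian activation noise
#'   (biphasic_reach only; default 0).
#' @param params [fv_params] shared by both muscles.
#' @return A [sim_result] with one joint (`"joint"`) and two muscles.
#' @export
generate_fixture <- function(kind = c("single_muscle", "coactivated",
                                      "biphasic_reach"),
                             n_steps = 501, seed = NULL, noise = 0,
                             params = fv_params(v_max = 1, r = 0.05,
                                                F_max = 300)) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop(
                     sprintf("generate_fixture: unknown kind '%s'", kind[1L]),
                     call. = FALSE))
  stopifnot(n_steps >= 3L)
  Tend <- 0.5
  time <- seq(0, Tend, length.out = n_steps)
  s <- time / Tend
  bump <- function(center, width) exp(-0.5 * ((s - center) / width)^2)
  if (kind == "single_muscle") {
    a_f <- rep(0.7, n_steps); a_e <- rep(0, n_steps)
    vn <- 0.8 * sin(pi * s)^2
  } else if (kind == "coactivated") {
    a_f <- rep(0.5, n_steps); a_e <- rep(0.5, n_steps)
    vn <- 0.8 * sin(2 * pi * s)
  } else {
    vn <- 0.7 * bump(0.3, 0.12) + 0.25 * bump(0.8, 0.07)
    a_f <- pmin(0.9 * bump(0.2, 0.1) + 0.5 * bump(0.75, 0.08), 1)
    a_e <- pmin(0.6 * bump(0.45, 0.1), 1)
    if (noise > 0) {
      if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv())) {
          get(".Random.seed", globalenv())
        }
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
      }
      a_f <- pmin(pmax(a_f + stats::rnorm(n_steps, sd = noise), 0), 1)
      a_e <- pmin(pmax(a_e + stats::rnorm(n_steps, sd = noise), 0), 1)
    }
  }
  qdot <- vn * params$theta_dot_max        # flexor-shortening-positive
  dt <- time[2L] - time[1L]
  q <- c(0, cumsum((qdot[-1L] + qdot[-n_steps]) / 2 * dt))
  gain_f <- pmax(.fv_raw(vn, params$d1, params$d2, params$d3), 0)
  gain_e <- pmax(.fv_raw(-vn, params$d1, params$d2, params$d3), 0)
  tq_f <- a_f * params$F_max * params$r * gain_f
  tq_e <- -a_e * params$F_max * params$r * gain_e
  qdd <- c(diff(qdot[1:2]) / dt,
           (qdot[-(1:2)] - qdot[1:(n_steps - 2L)]) / (2 * dt),
           diff(qdot[(n_steps - 1L):n_steps]) / dt)
  nm <- c("joint_flexor", "joint_extensor")
  sim_result(
    time = time, q = cbind(q), qdot = cbind(qdot), qddot = cbind(qdd),
    excitation = cbind(a_f, a_e), activation = cbind(a_f, a_e),
    torque = cbind(tq_f, tq_e), force_norm = cbind(a_f * gain_f, a_e * gain_e),
    v_norm = cbind(vn, -vn), torque_net = cbind(tq_f + tq_e),
    joints = "joint", muscle_names = nm,
    muscle_sign = stats::setNames(c(1, -1), nm),
    muscle_params = stats::setNames(list(params, params), nm),
    flexion_sign = c(joint = 1),
    meta = list(fixture = kind, seed = seed, noise = noise)
  )
}
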