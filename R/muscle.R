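#' Hill-type force-velocity parameters
#'
#' Bundles the shape constants and scaling of one muscle's force-velocity
#' relationship. The normalized curve is governed by three dimensionless
#' shape constants (`d1`, `d2`, `d3`); `v_max` (m/s) and the constant moment
#' arm `r` (m) set the velocity scale at the joint, and `F_max` (N) sets the
#' force scale. The maximum joint angular velocity is the derived quantity
#' `theta_dot_max = v_max / r` (rad/s).
#'
#' @param d1 Shortening-curvature constant (> 0). Default 4.
#' @param d2 Eccentric force plateau (> 1), the asymptotic normalized force
#'   during fast lengthening. Default 1.8.
#' @param d3 Lengthening-curvature constant (> 0). Default 30.24.
#' @param v_max Maximum shortening velocity in m/s (> 0).
#' @param r Moment arm in m (> 0), assumed constant.
#' @param F_max Maximum isometric force in N (> 0).
#'
#' @return An object of class `fv_params`.
#' @examples
#' p <- fv_params(v_max = 1, r = 0.05, F_max = 600)
#' p$theta_dot_max  # 20 rad/s
#' @export
fv_params <- function(d1 = 4, d2 = 1.8, d3 = 30.24,
                      v_max = 1, r = 0.05, F_max = 500) {
  stopifnot(
    is.numeric(d1), length(d1) == 1L, is.finite(d1), d1 > 0,
    is.numeric(d2), length(d2) == 1L, is.finite(d2), d2 > 1,
    is.numeric(d3), length(d3) == 1L, is.finite(d3), d3 > 0,
    is.numeric(v_max), length(v_max) == 1L, is.finite(v_max), v_max > 0,
    is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
    is.numeric(F_max), length(F_max) == 1L, is.finite(F_max), F_max > 0
  )
  structure(
    list(d1 = d1, d2 = d2, d3 = d3, v_max = v_max, r = r, F_max = F_max,
         theta_dot_max = v_max / r),
    class = "fv_params"
  )
}

#' @export
print.fv_params <- function(x, ...) {
  cat(sprintf(
    "<fv_params> d1=%g d2=%g d3=%g | v_max=%g m/s r=%g m F_max=%g N (theta_dot_max=%g rad/s)\n",
    x$d1, x$d2, x$d3, x$v_max, x$r, x$F_max, x$theta_dot_max))
  invisible(x)
}

#' Normalized Hill force-velocity gain
#'
#' Piecewise hyperbolic force-velocity relationship of an active muscle,
#' expressed against normalized velocity (positive = shortening):
#' for `v > 0` the gain is `(1 - v) / (1 + d1 * v)`; otherwise (lengthening)
#' it is `d2 - (d2 - 1) * (1 + v) / (1 - d3 * v)`. Both branches equal 1 at
#' `v = 0` (maximum isometric force), the shortening branch reaches 0 at
#' `v = 1`, and the lengthening branch approaches the eccentric plateau
#' `d2` for fast lengthening (exactly `d2` at `v = -1`).
#'
#' Values of `|v_norm| > 1` lie beyond the physiological range over which the
#' Hill model is calibrated; they are evaluated as the formula dictates but a
#' `"beyond physiological range"` warning is recorded.
#'
#' @param v_norm Numeric vector of normalized velocities (dimensionless,
#'   positive = shortening). Must be finite.
#' @param params An [fv_params] object (only the shape constants are used).
#' @return Numeric vector of dimensionless force multipliers.
#' @examples
#' p <- fv_params()
#' fv_gain(0, p)     # 1 (isometric)
#' fv_gain(1, p)     # 0
#' fv_gain(-1, p)    # 1.8 (eccentric plateau d2)
#' @export
fv_gain <- function(v_norm, params) {
  stopifnot(inherits(params, "fv_params"), is.numeric(v_norm))
  if (any(!is.finite(v_norm))) {
    stop("fv_gain: `v_norm` must be finite", call. = FALSE)
  }
  if (any(abs(v_norm) > 1)) {
    warning("fv_gain: velocity beyond physiological range (|v_norm| > 1)",
            call. = FALSE)
  }
  shortening <- v_norm > 0
  out <- numeric(length(v_norm))
  v <- v_norm[shortening]
  out[shortening] <- (1 - v) / (1 + params$d1 * v)
  v <- v_norm[!shortening]
  out[!shortening] <- params$d2 -
    (params$d2 - 1) * (1 + v) / (1 - params$d3 * v)
  out
}

#' One-sided derivative of the force-velocity gain
#'
#' Analytic derivative of [fv_gain] with respect to normalized velocity.
#' The curve has a kink at `v = 0`, so the branch must be chosen there:
#' `side = "right"` uses the shortening branch, `side = "left"` the
#' lengthening branch. Away from 0 both sides agree with the local branch.
#'
#' @inheritParams fv_gain
#' @param side `"right"` or `"left"` limit, relevant only at `v = 0`.
#' @return Numeric vector of slopes `d(fv_gain)/dv` (dimensionless).
#' @export
fv_gain_slope <- function(v_norm, params, side = c("right", "left")) {
  stopifnot(inherits(params, "fv_params"), is.numeric(v_norm),
            all(is.finite(v_norm)))
  side <- match.arg(side)
  use_short <- if (side == "right") v_norm >= 0 else v_norm > 0
  out <- numeric(length(v_norm))
  v <- v_norm[use_short]
  out[use_short] <- -(1 + params$d1) / (1 + params$d1 * v)^2
  v <- v_norm[!use_short]
  out[!use_short] <- -(params$d2 - 1) * (1 + params$d3) / (1 - params$d3 * v)^2
  out
}

#' Normalize a joint angular velocity to the muscle's velocity scale
#'
#' Converts a signed joint angular velocity (rad/s, positive in this
#' muscle's shortening direction) to the dimensionless velocity used by
#' [fv_gain]: `theta_dot / theta_dot_max` with `theta_dot_max = v_max / r`.
#'
#' @param theta_dot Joint angular velocity in rad/s, shortening-positive.
#' @param params An [fv_params] object.
#' @return Dimensionless normalized velocity.
#' @export
normalize_joint_velocity <- function(theta_dot, params) {
  stopifnot(inherits(params, "fv_params"), is.numeric(theta_dot))
  theta_dot * params$r / params$v_max
}

#' Activation state of one muscle
#'
#' Excitation-to-activation coupling is modelled as a cascade of three
#' identical first-order low-pass stages (third-order dynamics). The last
#' stage is the activation `a` consumed by the force model. A third-order
#' cascade gives realistic tens-of-millisecond rise delays and, unlike a
#' single first-order filter, a zero initial slope of `a` after a step in
#' excitation.
#'
#' @param stages Numeric vector of the three filter stages, each in \[0, 1\].
#' @param tau Time constant in s shared by the stages (default 0.02 s).
#' @param tau_fall Optional deactivation time constant in s; if supplied,
#'   it replaces `tau` whenever excitation is below the current activation
#'   (asymmetry hook; by default deactivation uses `tau`).
#' @return An object of class `activation_state`.
#' @export
activation_state <- function(stages = c(0, 0, 0), tau = 0.02,
                             tau_fall = NULL) {
  stopifnot(is.numeric(stages), length(stages) == 3L, all(is.finite(stages)),
            all(stages >= 0), all(stages <= 1),
            is.numeric(tau), length(tau) == 1L, tau > 0,
            is.null(tau_fall) || (is.numeric(tau_fall) && tau_fall > 0))
  structure(list(stages = stages, tau = tau, tau_fall = tau_fall),
            class = "activation_state")
}

#' Current activation level
#'
#' @param state An [activation_state].
#' @return The activation `a` (last cascade stage), dimensionless in \[0, 1\].
#' @export
activation <- function(state) {
  stopifnot(inherits(state, "activation_state"))
  state$stages[3L]
}

#' Advance activation dynamics by one time step
#'
#' Propagates the three-stage low-pass cascade under a constant excitation
#' `u` held over `dt`, using the exact solution of the linear cascade (no
#' integration error for constant input). The steady state of every stage is
#' `u`, so activation tracks excitation with a delay of roughly `3 * tau`.
#'
#' @param state An [activation_state].
#' @param u Excitation in \[0, 1\]; values outside are clipped with a warning.
#' @param dt Time step in s (> 0).
#' @return The updated [activation_state].
#' @export
activation_step <- function(state, u, dt) {
  stopifnot(inherits(state, "activation_state"),
            is.numeric(u), length(u) == 1L, is.finite(u),
            is.numeric(dt), length(dt) == 1L)
  if (!is.finite(dt) || dt <= 0) {
    stop("activation_step: `dt` must be positive", call. = FALSE)
  }
  if (u < 0 || u > 1) {
    warning("activation_step: excitation clipped to [0, 1]", call. = FALSE)
    u <- min(max(u, 0), 1)
  }
  tau <- state$tau
  if (!is.null(state$tau_fall) && u < state$stages[3L]) tau <- state$tau_fall
  # exact matrix exponential of the equal-tau cascade applied to (stages - u)
  h <- dt / tau
  e <- exp(-h)
  d <- state$stages - u
  new <- u + e * c(
    d[1L],
    d[2L] + h * d[1L],
    d[3L] + h * d[2L] + h^2 / 2 * d[1L]
  )
  state$stages <- pmin(pmax(new, 0), 1)
  state
}

#' Time derivative of the activation cascade
#'
#' Continuous-time right-hand side of the three-stage filter, used by the
#' simulator's coupled integrator. `stages` may stack several muscles as a
#' matrix (one column per muscle).
#'
#' @param stages Numeric vector of length 3, or a 3-row matrix.
#' @param u Excitation (scalar, or vector of one value per column).
#' @param tau Stage time constant in s.
#' @return Derivatives with the same shape as `stages`.
#' @keywords internal
activation_rhs <- function(stages, u, tau) {
  if (is.matrix(stages)) {
    rbind(u - stages[1L, ],
          stages[1L, ] - stages[2L, ],
          stages[2L, ] - stages[3L, ]) / tau
  } else {
    c(u - stages[1L], stages[1L] - stages[2L], stages[2L] - stages[3L]) / tau
  }
}

#' Muscle torque about its joint
#'
#' Torque magnitude produced by one muscle: activation times maximum
#' isometric force times the force-velocity gain, times the moment arm.
#' The force-length gain is deliberately omitted (velocity effects are
#' treated as dominant); a force-length hook can be supplied via `fl_gain`.
#' The result is non-negative (muscles pull; the anatomical direction sign
#' is applied by the caller), so the force-velocity gain is floored at zero
#' for shortening faster than `v_max`.
#'
#' @param a Activation in \[0, 1\].
#' @param theta_dot_signed Joint angular velocity in rad/s, signed so this
#'   muscle's shortening is positive.
#' @param params An [fv_params] object.
#' @param fl_gain Optional force-length multiplier (default 1).
#' @return Torque in N m (non-negative).
#' @examples
#' p <- fv_params(v_max = 1, r = 0.05, F_max = 600)
#' muscle_torque(1, 0, p)  # isometric maximum F_max * r = 30 N m
#' @export
muscle_torque <- function(a, theta_dot_signed, params, fl_gain = 1) {
  stopifnot(is.numeric(a), all(a >= 0), all(a <= 1))
  g <- fv_gain(normalize_joint_velocity(theta_dot_signed, params), params)
  a * params$F_max * params$r * pmax(g, 0) * fl_gain
}
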