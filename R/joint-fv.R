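#' Agonist/antagonist activation pair
#'
#' Holds the activation levels of an antagonistic muscle pair together with
#' the strength-ratio weight `b`, the ratio between maximum isometric
#' antagonist and agonist torques, which accounts for unequal muscle
#' strengths and moment arms (`b = 1` for an identical pair). The derived
#' net activation is `a_net = a_agonist - b * a_antagonist` (how much excess
#' activation the agonist has) and the co-activation is the activation level
#' simultaneously present in both muscles, `min(a_agonist, b * a_antagonist)`.
#'
#' @param a_agonist Agonist activation in \[0, 1\].
#' @param a_antagonist Antagonist activation in \[0, 1\].
#' @param b Strength-ratio weight (> 0), see [strength_ratio].
#' @return An object of class `activation_pair`.
#' @examples
#' net_and_coactivation(activation_pair(0.8, 0.5))  # a_net 0.3, co 0.5
#' @export
activation_pair <- function(a_agonist, a_antagonist, b = 1) {
  stopifnot(is.numeric(a_agonist), length(a_agonist) == 1L,
            a_agonist >= 0, a_agonist <= 1,
            is.numeric(a_antagonist), length(a_antagonist) == 1L,
            a_antagonist >= 0, a_antagonist <= 1,
            is.numeric(b), length(b) == 1L, is.finite(b), b > 0)
  structure(list(a_agonist = a_agonist, a_antagonist = a_antagonist, b = b),
            class = "activation_pair")
}

#' Strength-ratio weight of a muscle pair
#'
#' The ratio between the maximum isometric antagonist and agonist torques,
#' `(F_max_ant * r_ant) / (F_max_ag * r_ag)`.
#'
#' @param params_ant,params_ag [fv_params] of the antagonist and agonist.
#' @return Dimensionless weight `b`.
#' @export
strength_ratio <- function(params_ant, params_ag) {
  stopifnot(inherits(params_ant, "fv_params"), inherits(params_ag, "fv_params"))
  (params_ant$F_max * params_ant$r) / (params_ag$F_max * params_ag$r)
}

#' Net activation and co-activation of a pair
#'
#' @param pair An [activation_pair].
#' @return A list with `a_net = a_agonist - b * a_antagonist` and
#'   `co_activation = min(a_agonist, b * a_antagonist)`.
#' @export
net_and_coactivation <- function(pair) {
  stopifnot(inherits(pair, "activation_pair"))
  list(a_net = pair$a_agonist - pair$b * pair$a_antagonist,
       co_activation = min(pair$a_agonist, pair$b * pair$a_antagonist))
}

# Antagonist velocity rescaling: with unequal velocity scales, a normalized
# agonist velocity v corresponds to -v * theta_dot_max_ag / theta_dot_max_ant
# on the antagonist's normalized axis. rho = 1 for an identical pair.
.vel_scale_ratio <- function(params_ag, params_ant) {
  params_ag$theta_dot_max / params_ant$theta_dot_max
}

#' Instantaneous joint-fv value
#'
#' Net normalized joint torque at one normalized joint velocity:
#' `fv_joint(v) = a_agonist * FV_ag(v) - b * a_antagonist * FV_ant(-v)`.
#' The antagonist curve is the agonist-type curve reflected about both axes
#' (if one muscle shortens the other lengthens at the same speed, and their
#' torques act in opposite joint directions). `v` is normalized on the
#' agonist's velocity scale; an antagonist with a different `theta_dot_max`
#' is rescaled internally.
#'
#' @param v Normalized joint velocity (vector), positive in the agonist's
#'   shortening direction.
#' @param pair An [activation_pair].
#' @param params_ag Agonist [fv_params].
#' @param params_ant Antagonist [fv_params] (defaults to `params_ag`).
#' @return Net torque normalized by the agonist's maximum isometric torque.
#' @examples
#' p <- fv_params()
#' joint_fv_value(0, activation_pair(1, 0.5), p)  # 0.5
#' @export
joint_fv_value <- function(v, pair, params_ag, params_ant = params_ag) {
  stopifnot(inherits(pair, "activation_pair"))
  rho <- .vel_scale_ratio(params_ag, params_ant)
  pair$a_agonist * fv_gain(v, params_ag) -
    pair$b * pair$a_antagonist * fv_gain(-rho * v, params_ant)
}

#' Sampled joint-fv curve with its bounding space
#'
#' Samples the instantaneous joint-fv curve on a velocity grid together
#' with the ceiling (current agonist activation, antagonist silent) and
#' floor (agonist silent, current antagonist activation) curves that bound
#' the joint-fv space spanned as either activation varies in \[0, current\].
#' The curve lies between floor and ceiling at every grid point and passes
#' through `(0, a_net)`.
#'
#' @inheritParams joint_fv_value
#' @param grid Velocity samples, by default 401 uniform points on \[-1, 1\]
#'   (dense enough to resolve the kink at zero velocity).
#' @return An object of class `joint_fv_curve`: a list with a data frame
#'   `samples` (columns `v`, `f`, `ceiling`, `floor`), the `pair` and the
#'   parameter objects.
#' @export
joint_fv_curve <- function(pair, params_ag, params_ant = params_ag,
                           grid = seq(-1, 1, length.out = 401)) {
  stopifnot(inherits(pair, "activation_pair"))
  if (length(grid) == 0L || !is.numeric(grid)) {
    stop("joint_fv_curve: `grid` must be a non-empty numeric vector",
         call. = FALSE)
  }
  f <- joint_fv_value(grid, pair, params_ag, params_ant)
  up <- joint_fv_value(grid, activation_pair(pair$a_agonist, 0, pair$b),
                       params_ag, params_ant)
  lo <- joint_fv_value(
    grid, activation_pair(0, pair$a_antagonist, pair$b),
    params_ag, params_ant)
  structure(
    list(samples = data.frame(v = grid, f = f, ceiling = up, floor = lo),
         pair = pair, params_ag = params_ag, params_ant = params_ant),
    class = "joint_fv_curve"
  )
}

#' @export
print.joint_fv_curve <- function(x, ...) {
  nac <- net_and_coactivation(x$pair)
  cat(sprintf(
    "<joint_fv_curve> %d samples on [%g, %g]; a_ag=%g a_ant=%g b=%g (a_net=%g, co=%g)\n",
    nrow(x$samples), min(x$samples$v), max(x$samples$v),
    x$pair$a_agonist, x$pair$a_antagonist, x$pair$b,
    nac$a_net, nac$co_activation))
  invisible(x)
}

#' Classify operating points into joint-FV quadrants
#'
#' The four Cartesian quadrants of joint-FV space encode the joint's
#' instantaneous mechanical function (with `v` positive in the agonist's
#' shortening direction and `f` the normalized net torque):
#' \describe{
#'   \item{I}{`v > 0, f > 0` - agonist-direction motion powered by the
#'     agonist (power generation).}
#'   \item{IV}{`v > 0, f < 0` - agonist-direction motion resisted by the
#'     co-contracting antagonist (braking).}
#'   \item{III}{`v < 0, f < 0` - antagonist-direction motion powered by the
#'     antagonist.}
#'   \item{II}{`v < 0, f > 0` - antagonist-direction motion braked by the
#'     agonist.}
#' }
#' Points with `|v|` or `|f|` below `tol` are labelled `"on-axis"` (on the
#' torque axis both muscles work isometrically; on the velocity axis the
#' muscle torques balance).
#'
#' @param v,f Numeric vectors (recycled) of normalized velocity and torque.
#' @param tol On-axis tolerance (default 1e-3), which suppresses
#'   noise-driven quadrant flicker in trajectory metrics.
#' @return Character vector with values `"I"`, `"II"`, `"III"`, `"IV"`,
#'   `"on-axis"`.
#' @export
classify_quadrant <- function(v, f, tol = 1e-3) {
  stopifnot(is.numeric(v), is.numeric(f), all(is.finite(v)), all(is.finite(f)),
            is.numeric(tol), tol >= 0)
  n <- max(length(v), length(f))
  v <- rep_len(v, n); f <- rep_len(f, n)
  out <- rep("on-axis", n)
  off <- abs(v) >= tol & abs(f) >= tol
  out[off & v > 0 & f > 0] <- "I"
  out[off & v < 0 & f > 0] <- "II"
  out[off & v < 0 & f < 0] <- "III"
  out[off & v > 0 & f < 0] <- "IV"
  out
}

#' Local slope of the joint-fv curve
#'
#' Analytic one-sided derivative of the joint-fv curve with respect to
#' normalized velocity:
#' `a_agonist * FV'(v, side) + b * a_antagonist * FV'(-v, other side)`.
#' The slope is a proxy for intrinsic joint damping: any change in joint
#' velocity is counteracted by a torque change proportional to it. Because
#' both one-sided antagonist contributions carry the same (negative) sign as
#' the agonist's, co-contraction always steepens the local slope, most
#' strongly near zero velocity where the lengthening branch is steepest.
#'
#' @inheritParams joint_fv_value
#' @param side `"right"` or `"left"` one-sided limit; required at the kink
#'   `v = 0`, immaterial elsewhere.
#' @return Dimensionless slope `d(fv_joint)/dv` (negative).
#' @examples
#' p <- fv_params()
#' local_slope(0, activation_pair(1, 0), p, side = "right")  # -(1 + d1) = -5
#' @export
local_slope <- function(v, pair, params_ag, params_ant = params_ag,
                        side = c("right", "left")) {
  stopifnot(inherits(pair, "activation_pair"))
  side <- match.arg(side)
  other <- if (side == "right") "left" else "right"
  rho <- .vel_scale_ratio(params_ag, params_ant)
  pair$a_agonist * fv_gain_slope(v, params_ag, side) +
    pair$b * rho * pair$a_antagonist *
      fv_gain_slope(-rho * v, params_ant, other)
}
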