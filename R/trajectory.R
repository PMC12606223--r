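#' Select the agonist muscle of a joint from simulation data
#'
#' The agonist is a task-defined role, not a fixed anatomical label: it is
#' the muscle that produces the dominant positive mechanical power to
#' accelerate the load during the initial window of the movement (default
#' the first 0.05 s). Each muscle's power is its torque magnitude times the
#' joint angular velocity taken in that muscle's shortening-positive
#' convention (with constant moment arms this is proportional to fibre
#' power); powers are integrated over the window by the trapezoid rule.
#'
#' @param result A [sim_result].
#' @param joint Joint name.
#' @param window Integration window in s from movement onset.
#' @return A list with `muscle` (name), `role` (`"flexor"`/`"extensor"`),
#'   `sign` (world-frame orientation: shortening of the agonist maps to
#'   positive joint-FV velocity) and the two power integrals.
#' @export
select_agonist <- function(result, joint, window = 0.05) {
  stopifnot(inherits(result, "sim_result"), joint %in% result$joints)
  idx <- result$time <= min(window, max(result$time)) + 1e-12
  if (sum(idx) < 2L) {
    stop("select_agonist: result does not cover the selection window",
         call. = FALSE)
  }
  muscles <- grep(paste0("^", joint, "_"), result$muscle_names, value = TRUE)
  tt <- result$time[idx]
  qd <- result$qdot[idx, joint]
  pow <- vapply(muscles, function(m) {
    # world torque x world angular velocity = muscle power (both signs flip)
    p <- result$torque[idx, m] * qd
    k <- length(p)
    sum(diff(tt) * (p[-k] + p[-1L]) / 2)
  }, numeric(1))
  if (all(pow <= 0)) {
    stop(sprintf(
      "select_agonist: ambiguous agonist at %s (power integrals %s <= 0); no muscle accelerates the load in the first %.3f s",
      joint, paste(signif(pow, 3), collapse = ", "), window), call. = FALSE)
  }
  m <- muscles[which.max(pow)]
  list(muscle = m, role = sub(paste0(joint, "_"), "", m),
       sign = unname(result$muscle_sign[m]), power = pow)
}

#' Extract the joint-FV trajectory of one joint
#'
#' Converts a simulation into a sequence of joint-FV operating points:
#' `v` is the joint angular velocity normalized by the agonist's maximum
#' joint velocity, oriented so the agonist's shortening is positive, and
#' `f` is the net muscle torque about the joint normalized by the agonist's
#' maximum isometric torque `F_max * r` (which makes simulated trajectories
#' dimensionally identical to theoretical joint-fv curves). Each point is
#' quadrant-classified with [classify_quadrant].
#'
#' @param result A [sim_result].
#' @param joint Joint name.
#' @param agonist Agonist muscle name; by default chosen by
#'   [select_agonist].
#' @param tol On-axis tolerance for quadrant classification.
#' @return A data frame of class `jointfv_trajectory` with columns `t`,
#'   `v`, `f`, `quadrant` and attributes `joint` and `agonist`.
#' @export
extract_trajectory <- function(result, joint, agonist = NULL, tol = 1e-3) {
  stopifnot(inherits(result, "sim_result"))
  if (!joint %in% result$joints) {
    stop(sprintf("extract_trajectory: unknown joint '%s' (have: %s)",
                 joint, paste(result$joints, collapse = ", ")), call. = FALSE)
  }
  if (is.null(agonist)) agonist <- select_agonist(result, joint)$muscle
  stopifnot(agonist %in% result$muscle_names)
  sgn <- unname(result$muscle_sign[agonist])
  p <- result$muscle_params[[agonist]]
  v <- sgn * result$qdot[, joint] / p$theta_dot_max
  f <- sgn * result$torque_net[, joint] / (p$F_max * p$r)
  out <- data.frame(t = result$time, v = v, f = f,
                    quadrant = classify_quadrant(v, f, tol))
  attr(out, "joint") <- joint
  attr(out, "agonist") <- agonist
  class(out) <- c("jointfv_trajectory", "data.frame")
  out
}

#' Shape metrics of a joint-FV trajectory
#'
#' Deterministic descriptors of a closed-ish path through joint-FV space:
#' \describe{
#'   \item{quadrant_sequence}{Run-length-encoded sequence of quadrant
#'     labels, on-axis points dropped.}
#'   \item{signed_area}{Shoelace area of the (v, f) polygon; negative =
#'     clockwise under the joint-FV axis convention.}
#'   \item{rotation}{`"clockwise"` or `"anticlockwise"` from the area sign.}
#'   \item{x_crossings}{Number of sign changes of `f` (crossings of the
#'     velocity axis, i.e. reversals of net torque direction).}
#'   \item{closure_distance}{Euclidean distance between first and last
#'     points (0 for a closed loop).}
#' }
#'
#' @param traj A `jointfv_trajectory` or any data frame with columns `v`,
#'   `f` (and optionally `quadrant`; recomputed if absent).
#' @param tol On-axis tolerance used if quadrants must be recomputed.
#' @return A list with the five metrics.
#' @export
trajectory_metrics <- function(traj, tol = 1e-3) {
  stopifnot(is.data.frame(traj), all(c("v", "f") %in% names(traj)))
  if (nrow(traj) < 3L) {
    stop("trajectory_metrics: need at least 3 points", call. = FALSE)
  }
  v <- traj$v; f <- traj$f
  quad <- if ("quadrant" %in% names(traj)) as.character(traj$quadrant) else
    classify_quadrant(v, f, tol)
  qs <- rle(quad[quad != "on-axis"])$values
  # shoelace over the implicitly closed polygon
  area <- sum(v * c(f[-1L], f[1L]) - c(v[-1L], v[1L]) * f) / 2
  sgn_f <- sign(f)[sign(f) != 0]
  list(
    quadrant_sequence = qs,
    signed_area = area,
    rotation = if (area < 0) "clockwise" else "anticlockwise",
    x_crossings = sum(diff(sgn_f) != 0),
    closure_distance = sqrt((v[length(v)] - v[1L])^2 +
                              (f[length(f)] - f[1L])^2)
  )
}

#' Read a generic per-joint muscle time series as a simulation result
#'
#' Adapter for externally produced simulator output. The CSV/data frame
#' must be in long-by-muscle format with columns `time`, `joint`, `muscle`
#' (role `"flexor"`/`"extensor"` or full `<joint>_<role>` name), `angle`
#' (rad), `velocity` (rad/s, world convention), `activation` and `torque`
#' (N m, signed world convention). Muscle parameters and flexion signs per
#' joint must be supplied to interpret the series.
#'
#' @param x A data frame or a path to a CSV file.
#' @param muscle_params Named list of [fv_params], one per
#'   `<joint>_<role>` muscle.
#' @param flexion_sign Named +1/-1 per joint (default +1).
#' @return A [sim_result] (excitation mirrors activation; accelerations by
#'   central differences; hand series absent).
#' @export
as_sim_result <- function(x, muscle_params, flexion_sign = NULL) {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  need <- c("time", "joint", "muscle", "angle", "velocity", "activation",
            "torque")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("as_sim_result: missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  joints <- unique(df$joint)
  df$muscle <- ifelse(grepl("_", df$muscle), df$muscle,
                      paste(df$joint, df$muscle, sep = "_"))
  muscle_names <- as.vector(t(outer(joints, c("flexor", "extensor"),
                                    paste, sep = "_")))
  if (!setequal(unique(df$muscle), muscle_names)) {
    stop("as_sim_result: expected one flexor and one extensor row set per joint",
         call. = FALSE)
  }
  stopifnot(all(muscle_names %in% names(muscle_params)))
  if (is.null(flexion_sign)) {
    flexion_sign <- stats::setNames(rep(1, length(joints)), joints)
  }
  time <- sort(unique(df$time))
  n <- length(time)
  grab <- function(col, by, keys) {
    out <- matrix(NA_real_, n, length(keys), dimnames = list(NULL, keys))
    for (k in keys) {
      sub <- df[df[[by]] == k, c("time", col)]
      sub <- sub[!duplicated(sub$time), ]
      if (nrow(sub) != n) {
        stop(sprintf("as_sim_result: series '%s' for '%s' does not cover the time grid",
                     col, k), call. = FALSE)
      }
      out[, k] <- sub[[col]][order(sub$time)]
    }
    out
  }
  q <- grab("angle", "joint", joints)
  qdot <- grab("velocity", "joint", joints)
  act <- grab("activation", "muscle", muscle_names)
  tq <- grab("torque", "muscle", muscle_names)
  msign <- rep(unname(flexion_sign[joints]), each = 2L) * c(1, -1)
  names(msign) <- muscle_names
  tnet <- sapply(joints, function(j) {
    rowSums(tq[, grep(paste0("^", j, "_"), muscle_names), drop = FALSE])
  })
  if (!is.matrix(tnet)) tnet <- matrix(tnet, ncol = length(joints))
  vnorm <- sapply(muscle_names, function(m) {
    p <- muscle_params[[m]]
    msign[m] * qdot[, sub("_(flexor|extensor)$", "", m)] * p$r / p$v_max
  })
  if (!is.matrix(vnorm)) vnorm <- matrix(vnorm, ncol = length(muscle_names))
  dtv <- diff(time)
  qdd <- apply(qdot, 2L, function(col) {
    c(diff(col[1:2]) / dtv[1L],
      (col[-(1:2)] - col[1:(n - 2L)]) / (time[-(1:2)] - time[1:(n - 2L)]),
      diff(col[(n - 1L):n]) / dtv[n - 1L])
  })
  fn <- sapply(muscle_names, function(m) {
    p <- muscle_params[[m]]
    abs(tq[, m]) / (p$F_max * p$r)
  })
  if (!is.matrix(fn)) fn <- matrix(fn, ncol = length(muscle_names))
  sim_result(time = time, q = q, qdot = qdot, qddot = qdd,
             excitation = act, activation = act, torque = tq,
             force_norm = fn, v_norm = vnorm, torque_net = tnet,
             joints = joints, muscle_names = muscle_names,
             muscle_sign = msign, muscle_params = muscle_params[muscle_names],
             flexion_sign = flexion_sign,
             meta = list(source = "external"))
}
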