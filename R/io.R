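#' Write a simulation result to disk
#'
#' Serializes a [sim_result] as a tidy CSV of all time series (one row per
#' time step per series) plus a JSON metadata sidecar holding the muscle
#' parameters, sign conventions and run metadata. This pair of files is the
#' on-disk contract between the simulator and the analysis/visualization
#' layers; [read_result] restores an equivalent object.
#'
#' @param result A [sim_result].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_result <- function(result, dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(mat, group, series) {
    if (is.null(mat)) return(NULL)
    data.frame(time = rep(result$time, ncol(mat)),
               group = group, series = series,
               name = rep(colnames(mat) %||% c("x", "y"), each = nrow(mat)),
               value = as.vector(mat))
  }
  hand_named <- function(m) {
    if (is.null(m)) return(NULL)
    colnames(m) <- c("x", "y"); m
  }
  df <- rbind(
    long(result$q, "joint", "angle"),
    long(result$qdot, "joint", "velocity"),
    long(result$qddot, "joint", "acceleration"),
    long(result$torque_net, "joint", "net_torque"),
    long(result$excitation, "muscle", "excitation"),
    long(result$activation, "muscle", "activation"),
    long(result$torque, "muscle", "torque"),
    long(result$force_norm, "muscle", "force_norm"),
    long(result$v_norm, "muscle", "v_norm"),
    long(hand_named(result$hand_pos), "hand", "position"),
    long(hand_named(result$hand_vel), "hand", "velocity"),
    long(hand_named(result$ext_force), "hand", "ext_force")
  )
  utils::write.csv(df, file.path(dir, "series.csv"), row.names = FALSE)
  meta <- list(
    joints = result$joints,
    muscle_names = result$muscle_names,
    muscle_sign = as.list(result$muscle_sign),
    flexion_sign = as.list(result$flexion_sign),
    muscle_params = lapply(result$muscle_params, function(p) {
      unclass(p)[c("d1", "d2", "d3", "v_max", "r", "F_max")]
    }),
    meta = result$meta
  )
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}

#' Read a simulation result written by [write_result]
#'
#' @param dir Directory holding `series.csv` and `metadata.json`.
#' @return A [sim_result].
#' @export
read_result <- function(dir) {
  csv <- file.path(dir, "series.csv")
  js <- file.path(dir, "metadata.json")
  if (!file.exists(csv) || !file.exists(js)) {
    stop(sprintf("read_result: '%s' does not contain series.csv + metadata.json",
                 dir), call. = FALSE)
  }
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("time", "group", "series", "name", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("read_result: series.csv is missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  }
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  time <- sort(unique(df$time))
  wide <- function(group, series, names_exp) {
    sub <- df[df$group == group & df$series == series, ]
    if (nrow(sub) == 0L) return(NULL)
    m <- sapply(names_exp, function(nm) {
      s <- sub[sub$name == nm, ]
      s$value[order(s$time)]
    })
    if (!is.matrix(m)) m <- matrix(m, ncol = length(names_exp))
    colnames(m) <- names_exp
    m
  }
  joints <- meta$joints
  mn <- meta$muscle_names
  params <- lapply(meta$muscle_params, function(p) {
    fv_params(p$d1, p$d2, p$d3, p$v_max, p$r, p$F_max)
  })
  sim_result(
    time = time,
    q = wide("joint", "angle", joints),
    qdot = wide("joint", "velocity", joints),
    qddot = wide("joint", "acceleration", joints),
    torque_net = wide("joint", "net_torque", joints),
    excitation = wide("muscle", "excitation", mn),
    activation = wide("muscle", "activation", mn),
    torque = wide("muscle", "torque", mn),
    force_norm = wide("muscle", "force_norm", mn),
    v_norm = wide("muscle", "v_norm", mn),
    hand_pos = wide("hand", "position", c("x", "y")),
    hand_vel = wide("hand", "velocity", c("x", "y")),
    ext_force = wide("hand", "ext_force", c("x", "y")),
    joints = joints, muscle_names = mn,
    muscle_sign = vapply(meta$muscle_sign[mn], as.numeric, numeric(1)),
    muscle_params = params[mn],
    flexion_sign = vapply(meta$flexion_sign[joints], as.numeric, numeric(1)),
    meta = meta$meta
  )
}

#' Write a joint-FV trajectory and its metrics
#'
#' @param traj A `jointfv_trajectory` (see [extract_trajectory]).
#' @param metrics Output of [trajectory_metrics] (optional).
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_trajectory <- function(traj, metrics = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- as.data.frame(traj)
  out$joint <- attr(traj, "joint") %||% NA_character_
  out$agonist <- attr(traj, "agonist") %||% NA_character_
  utils::write.csv(out, file.path(dir, "trajectory.csv"), row.names = FALSE)
  if (!is.null(metrics)) {
    jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
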