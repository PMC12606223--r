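#' Area of the joint-fv space between floor and ceiling
#'
#' Trapezoid-rule integral of `ceiling(v) - floor(v)` over the velocity
#' grid; a scalar measure of the rendered joint-fv space that is monotone
#' non-decreasing in either activation.
#'
#' @inheritParams joint_fv_curve
#' @return Non-negative scalar.
#' @export
joint_fv_space_area <- function(pair, params_ag, params_ant = params_ag,
                                grid = seq(-1, 1, length.out = 401)) {
  cur <- joint_fv_curve(pair, params_ag, params_ant, grid)
  gap <- cur$samples$ceiling - cur$samples$floor
  dv <- diff(grid)
  sum(dv * (gap[-length(gap)] + gap[-1L]) / 2)
}

# Joint positions of the 3-link chain for the arm inset.
.arm_points <- function(lengths, anchor, q) {
  th <- cumsum(q)
  x <- anchor[1L] + cumsum(c(0, lengths * cos(th)))
  y <- anchor[2L] + cumsum(c(0, lengths * sin(th)))
  data.frame(x = x, y = y)
}

#' Render one joint-FV frame
#'
#' Draws the instantaneous joint-fv curve (solid black) between the upper
#' and lower limits of the joint-fv space (dashed black ceiling, dashed
#' grey floor) with the space shaded, the trajectory trail up to the frame
#' (grey dots), the current operating point (black dot), quadrant labels,
#' and - when the result carries arm geometry - a small posture inset with
#' the target marker. Axis limits are fixed from the whole trajectory so
#' frames of one animation share axes. Rendering is a pure function of
#' (data, style): identical inputs yield identical plots.
#'
#' The operating point is asserted to lie on the instantaneous joint-fv
#' curve (the simulated torque equals the theoretical curve value at the
#' simulated velocity); a violation signals inconsistent inputs and raises
#' a warning.
#'
#' @param result A [sim_result].
#' @param joint Joint name.
#' @param index Time index (1-based) of the frame.
#' @param agonist Optional agonist muscle name (default: [select_agonist]).
#' @param trail Draw the trajectory trail up to `index`.
#' @param inset Draw the arm-posture inset (ignored when geometry is
#'   unavailable).
#' @param xlim,ylim Optional fixed axis limits.
#' @param check_tol Tolerance of the point-on-curve assertion.
#' @return A ggplot/patchwork object.
#' @export
render_joint_fv_frame <- function(result, joint, index, agonist = NULL,
                                  trail = TRUE, inset = TRUE,
                                  xlim = NULL, ylim = NULL,
                                  check_tol = 1e-6) {
  stopifnot(inherits(result, "sim_result"))
  n <- length(result$time)
  if (!is.numeric(index) || index < 1L || index > n) {
    stop(sprintf("render_joint_fv_frame: index %s outside 1..%d",
                 as.character(index)[1L], n), call. = FALSE)
  }
  index <- as.integer(index)
  if (is.null(agonist)) agonist <- select_agonist(result, joint)$muscle
  traj <- extract_trajectory(result, joint, agonist)
  muscles <- grep(paste0("^", joint, "_"), result$muscle_names, value = TRUE)
  antagonist <- setdiff(muscles, agonist)
  p_ag <- result$muscle_params[[agonist]]
  p_ant <- result$muscle_params[[antagonist]]
  b <- strength_ratio(p_ant, p_ag)
  pair <- activation_pair(result$activation[index, agonist],
                          result$activation[index, antagonist], b)
  cur <- suppressWarnings(joint_fv_curve(pair, p_ag, p_ant))
  v_now <- traj$v[index]; f_now <- traj$f[index]
  f_theory <- suppressWarnings(joint_fv_value(v_now, pair, p_ag, p_ant))
  # negative FV gains (beyond v_max) are floored in the torque model
  if (abs(v_now) <= 1 && abs(f_now - f_theory) > check_tol) {
    warning(sprintf(
      "render_joint_fv_frame: operating point off the joint-fv curve by %.2e",
      abs(f_now - f_theory)), call. = FALSE)
  }
  full <- suppressWarnings(
    joint_fv_curve(activation_pair(1, 1, b), p_ag, p_ant)$samples)
  if (is.null(xlim)) xlim <- range(c(-1, 1, traj$v))
  if (is.null(ylim)) ylim <- range(c(full$ceiling, full$floor, traj$f))
  qlab <- data.frame(
    v = c(0.9, -0.9, -0.9, 0.9) * max(abs(xlim)),
    f = c(0.9, 0.9, -0.9, -0.9) * max(abs(ylim)),
    lab = c("I", "II", "III", "IV"))
  s <- cur$samples
  main <- ggplot2::ggplot(s, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$floor,
                                      ymax = .data$ceiling),
                         fill = "grey85", alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ceiling), colour = "black",
                       linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$floor), colour = "grey50",
                       linetype = "dashed", linewidth = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f), colour = "black",
                       linewidth = 0.7) +
    ggplot2::geom_text(data = qlab,
                       ggplot2::aes(x = .data$v, y = .data$f,
                                    label = .data$lab),
                       colour = "grey40", size = 4) +
    ggplot2::coord_cartesian(xlim = xlim, ylim = ylim) +
    ggplot2::labs(
      x = "normalized joint velocity (agonist shortening +)",
      y = "normalized net torque",
      title = sprintf("%s  (t = %.3f s)", joint, result$time[index])) +
    ggplot2::theme_classic(base_size = 10)
  if (trail && index > 1L) {
    main <- main + ggplot2::geom_point(
      data = traj[seq_len(index - 1L), ],
      ggplot2::aes(x = .data$v, y = .data$f),
      colour = "grey65", size = 0.6)
  }
  main <- main + ggplot2::annotate("point", x = v_now, y = f_now,
                                   colour = "black", size = 2.5)
  lengths <- result$meta$model_lengths
  if (inset && !is.null(lengths) && ncol(result$q) == 3L) {
    anchor <- result$meta$model_anchor %||% c(0, 0)
    pts <- .arm_points(lengths, anchor, result$q[index, ])
    reach <- sum(lengths)
    ip <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_path(linewidth = 1, colour = "black") +
      ggplot2::geom_point(size = 1, colour = "black") +
      ggplot2::coord_fixed(xlim = anchor[1L] + c(-reach, reach),
                           ylim = anchor[2L] + c(-0.2, reach)) +
      ggplot2::theme_void()
    tgt <- result$meta$target
    if (!is.null(tgt)) {
      ip <- ip + ggplot2::annotate("point", x = tgt[1L], y = tgt[2L],
                                   colour = "red", size = 2)
    }
    return(main + patchwork::inset_element(ip, 0.72, 0.72, 0.99, 0.99,
                                           align_to = "panel"))
  }
  main
}

#' Save a plot as a PNG file
#'
#' @param plot A ggplot/patchwork object.
#' @param path Output file path.
#' @param width,height Size in inches.
#' @param dpi Resolution.
#' @return `path`, invisibly.
#' @export
save_frame <- function(plot, path, width = 5, height = 5, dpi = 110) {
  grDevices::png(path, width = width * dpi, height = height * dpi, res = dpi,
                 type = "cairo")
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}

#' Animate a joint's path through joint-FV space
#'
#' Writes `ceiling(duration * fps)` sequential joint-FV frames as numbered
#' PNG files with axes fixed across frames. If `out` ends in `.gif` and a
#' `python` interpreter with the `imageio` module is available on the PATH,
#' the frames are additionally assembled into an animated GIF; otherwise
#' the frame directory alone is produced (with a message).
#'
#' @param result A [sim_result] with at least two samples.
#' @param joint Joint name.
#' @param fps Frames per second of the animation.
#' @param out Output directory for frames, or a `.gif` file path.
#' @param agonist Optional agonist override.
#' @return Invisible list with `frames` (PNG paths) and `gif` (path or
#'   NULL).
#' @export
animate_joint_fv <- function(result, joint, fps = 25, out, agonist = NULL) {
  stopifnot(inherits(result, "sim_result"))
  if (length(result$time) < 2L) {
    stop("animate_joint_fv: result has fewer than 2 samples", call. = FALSE)
  }
  duration <- max(result$time) - min(result$time)
  n_frames <- ceiling(duration * fps)
  want_gif <- grepl("\\.gif$", out, ignore.case = TRUE)
  frame_dir <- if (want_gif) file.path(tempdir(), "jointfv_frames") else out
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(agonist)) agonist <- select_agonist(result, joint)$muscle
  traj <- extract_trajectory(result, joint, agonist)
  muscles <- grep(paste0("^", joint, "_"), result$muscle_names, value = TRUE)
  p_ag <- result$muscle_params[[agonist]]
  p_ant <- result$muscle_params[[setdiff(muscles, agonist)]]
  b <- strength_ratio(p_ant, p_ag)
  full <- suppressWarnings(
    joint_fv_curve(activation_pair(1, 1, b), p_ag, p_ant)$samples)
  xlim <- range(c(-1, 1, traj$v))
  ylim <- range(c(full$ceiling, full$floor, traj$f))
  frame_times <- min(result$time) + (seq_len(n_frames) - 1L) / fps
  paths <- character(n_frames)
  for (k in seq_len(n_frames)) {
    idx <- which.min(abs(result$time - frame_times[k]))
    paths[k] <- file.path(frame_dir, sprintf("frame_%04d.png", k))
    p <- render_joint_fv_frame(result, joint, idx, agonist = agonist,
                               xlim = xlim, ylim = ylim)
    save_frame(p, paths[k])
  }
  gif <- NULL
  if (want_gif) {
    gif <- .assemble_gif(paths, out, fps)
    if (is.null(gif)) {
      message("animate_joint_fv: no GIF encoder available; frames kept in ",
              frame_dir)
    }
  }
  invisible(list(frames = paths, gif = gif))
}

# Assemble PNG frames into a GIF via the system python's imageio, if present.
.assemble_gif <- function(frames, out, fps) {
  py <- Sys.which("python")
  if (py == "") return(NULL)
  listing <- paste(sprintf('"%s"', frames), collapse = ",")
  script <- sprintf(paste0(
    "import imageio.v2 as iio\n",
    "frames=[%s]\n",
    "iio.mimsave(r'%s', [iio.imread(f) for f in frames], duration=%g, loop=0)\n"),
    listing, out, 1 / fps)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- tryCatch(system2(py, sf, stdout = FALSE, stderr = FALSE),
                     error = function(e) 1L)
  if (identical(status, 0L) && file.exists(out)) out else NULL
}

#' Time-series panels of a simulation
#'
#' Stacked panels of selected series: `angle` (per joint, rad), `velocity`
#' (per muscle, normalized shortening velocity), `activation` (per muscle),
#' `force` (per muscle, normalized force), `torque` (net muscle torque per
#' joint, N m) and `torque_rate` (its finite-difference time derivative,
#' N m/s). Flexors are drawn solid, extensors dashed; colour encodes the
#' joint.
#'
#' @param result A [sim_result].
#' @param panels Character subset of the panel names above.
#' @return A ggplot object.
#' @export
plot_time_series <- function(result,
                             panels = c("angle", "velocity", "activation",
                                        "force", "torque")) {
  stopifnot(inherits(result, "sim_result"))
  valid <- c("angle", "velocity", "activation", "force", "torque",
             "torque_rate")
  bad <- setdiff(panels, valid)
  if (length(bad) > 0L) {
    stop(sprintf("plot_time_series: unknown panel(s): %s (valid: %s)",
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  joint_of <- function(m) sub("_(flexor|extensor)$", "", m)
  role_of <- function(m) sub("^.*_", "", m)
  jl <- function(mat, panel) {
    data.frame(time = rep(result$time, ncol(mat)), panel = panel,
               joint = rep(colnames(mat), each = nrow(mat)), role = "joint",
               value = as.vector(mat))
  }
  ml <- function(mat, panel) {
    data.frame(time = rep(result$time, ncol(mat)), panel = panel,
               joint = rep(joint_of(colnames(mat)), each = nrow(mat)),
               role = rep(role_of(colnames(mat)), each = nrow(mat)),
               value = as.vector(mat))
  }
  pieces <- list()
  for (p in panels) {
    pieces[[p]] <- switch(
      p,
      angle = jl(result$q, "angle (rad)"),
      velocity = ml(result$v_norm, "shortening velocity (norm.)"),
      activation = ml(result$activation, "activation"),
      force = ml(result$force_norm, "normalized force"),
      torque = jl(result$torque_net, "net muscle torque (N m)"),
      torque_rate = {
        dtv <- diff(result$time)
        tr <- apply(result$torque_net, 2L, function(col) {
          c(0, diff(col) / dtv)
        })
        colnames(tr) <- colnames(result$torque_net)
        jl(tr, "torque rate (N m/s)")
      })
  }
  df <- do.call(rbind, pieces)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  df$line_id <- paste(df$joint, df$role)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$joint,
                                   linetype = .data$role,
                                   group = .data$line_id)) +
    ggplot2::geom_line(linewidth = 0.5) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1L,
                        strip.position = "left") +
    ggplot2::scale_linetype_manual(
      values = c(flexor = "solid", extensor = "dashed", joint = "solid")) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_bw(base_size = 10) +
    ggplot2::theme(strip.placement = "outside",
                   strip.background = ggplot2::element_blank())
}
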