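# Movement-path summary statistics: velocity and the circular standard
# deviation of turning angles, with the minimum-duration path filter.

#' Movement path container
#'
#' Stores tracked paths as a long data frame (one row per frame) with a
#' fixed frame rate.
#'
#' @param df Data frame with columns `id`, `frame`, `x`, `y`.
#' @param fps Frames per second (default 25, i.e. 500 frames over 20 s).
#'
#' @return A data frame of class `movement_paths` with attribute `fps`.
#' @export
as_movement_paths <- function(df, fps = 25) {
  need <- c("id", "frame", "x", "y")
  if (!all(need %in% names(df))) {
    stop("movement paths need columns: ", paste(need, collapse = ", "))
  }
  if (fps <= 0) stop("fps must be > 0")
  df <- df[order(df$id, df$frame), need]
  structure(df, fps = fps, class = c("movement_paths", "data.frame"))
}

paths_fps <- function(paths, fps = NULL) {
  if (!is.null(fps)) return(fps)
  f <- attr(paths, "fps")
  if (is.null(f)) 25 else f
}

#' Filter paths by minimum duration
#'
#' Keeps paths observed for at least `min_duration` seconds, with duration
#' `(n_frames - 1) / fps`. The default 4 s threshold discards tracks too
#' short for reliable movement statistics.
#'
#' @param paths A [as_movement_paths()] data frame.
#' @param min_duration Minimum duration in seconds (>= 0).
#' @param fps Frames per second (defaults to the container attribute).
#'
#' @return The filtered `movement_paths` object.
#' @export
filter_paths <- function(paths, min_duration = 4, fps = NULL) {
  if (min_duration < 0) stop("min_duration must be >= 0")
  fps <- paths_fps(paths, fps)
  n <- table(paths$id)
  keep <- names(n)[(as.numeric(n) - 1) / fps >= min_duration]
  out <- paths[paths$id %in% keep, , drop = FALSE]
  structure(out, fps = fps, class = c("movement_paths", "data.frame"))
}

#' Path velocity
#'
#' Mean per-step displacement divided by the frame interval (mean step
#' speed, the trajectory-analysis convention); units follow the input
#' coordinates per second.
#'
#' @param path Data frame with columns `x` and `y` for one path (>= 2
#'   frames).
#' @param fps Frames per second.
#'
#' @return Speed (coordinate units per second).
#' @export
path_velocity <- function(path, fps = NULL) {
  fps <- paths_fps(path, fps)
  if (!is.finite(fps) || fps <= 0) stop("frame interval must be positive")
  if (nrow(path) < 2) stop("at least 2 frames are required")
  steps <- sqrt(diff(path$x)^2 + diff(path$y)^2)
  mean(steps) * fps
}

#' Circular standard deviation of turning angles
#'
#' Turning angles are the signed heading changes between consecutive
#' steps (zero-length steps carry no heading and are skipped). The
#' circular s.d. is \eqn{\sqrt{-2 \ln \bar R}} with \eqn{\bar R} the mean
#' resultant length of the angles (floored at 1e-12, so uniform angles
#' give a large finite value rather than infinity).
#'
#' @param path Data frame with columns `x` and `y` for one path (>= 3
#'   frames).
#' @return Circular s.d. in radians, or `NA` (with a warning) when fewer
#'   than two valid turning angles exist.
#' @export
turning_angle_circular_sd <- function(path) {
  if (nrow(path) < 3) stop("at least 3 frames are required")
  dx <- diff(path$x)
  dy <- diff(path$y)
  keep <- dx != 0 | dy != 0
  head_ang <- atan2(dy[keep], dx[keep])
  if (length(head_ang) < 2) {
    warning("fewer than 2 valid turning angles; circular s.d. undefined")
    return(NA_real_)
  }
  turns <- diff(head_ang)
  turns <- atan2(sin(turns), cos(turns)) # wrap to (-pi, pi]
  if (length(turns) < 2) {
    warning("fewer than 2 valid turning angles; circular s.d. undefined")
    return(NA_real_)
  }
  rbar <- sqrt(mean(cos(turns))^2 + mean(sin(turns))^2)
  sqrt(-2 * log(max(rbar, 1e-12)))
}

#' Per-path movement statistics
#'
#' Computes, for every path, the number of frames, duration, velocity,
#' circular s.d. of turning angles and net displacement.
#'
#' @param paths A [as_movement_paths()] data frame.
#' @param min_duration Optional duration filter applied first (seconds);
#'   `NULL` keeps all paths.
#' @param fps Frames per second.
#'
#' @return Data frame with columns `id`, `n_frames`, `duration_s`,
#'   `velocity`, `circ_sd`, `net_displacement`.
#' @export
path_stats <- function(paths, min_duration = NULL, fps = NULL) {
  fps <- paths_fps(paths, fps)
  if (!is.null(min_duration)) {
    paths <- filter_paths(paths, min_duration, fps)
  }
  ids <- unique(paths$id)
  rows <- lapply(ids, function(i) {
    p <- paths[paths$id == i, , drop = FALSE]
    data.frame(
      id = i, n_frames = nrow(p), duration_s = (nrow(p) - 1) / fps,
      velocity = if (nrow(p) >= 2) path_velocity(p, fps) else NA_real_,
      circ_sd = if (nrow(p) >= 3) {
        suppressWarnings(turning_angle_circular_sd(p))
      } else NA_real_,
      net_displacement = sqrt((p$x[nrow(p)] - p$x[1])^2 +
                                (p$y[nrow(p)] - p$y[1])^2)
    )
  })
  do.call(rbind, rows)
}

#' Population-level movement summary
#'
#' Mean velocity and circular s.d. across all paths of one sample, the
#' level at which movement is analysed.
#'
#' @param stats A [path_stats()] data frame (or `movement_paths`, which is
#'   summarised first).
#' @param ... Passed on to [path_stats()].
#' @return One-row data frame with `n_paths`, `velocity`, `circ_sd`.
#' @export
population_movement <- function(stats, ...) {
  if (inherits(stats, "movement_paths")) stats <- path_stats(stats, ...)
  data.frame(n_paths = nrow(stats),
             velocity = mean(stats$velocity, na.rm = TRUE),
             circ_sd = mean(stats$circ_sd, na.rm = TRUE))
}

#' Read / write movement paths CSV
#'
#' On-disk format: CSV with columns `id,frame,x,y`.
#'
#' @param path File path.
#' @param fps Frames per second recorded on read.
#' @return `read_paths()` returns a `movement_paths` object;
#'   `write_paths()` returns `path` invisibly.
#' @export
read_paths <- function(path, fps = 25) {
  as_movement_paths(read.csv(path, stringsAsFactors = FALSE), fps = fps)
}

#' @param x A `movement_paths` object.
#' @rdname read_paths
#' @export
write_paths <- function(x, path) {
  write.csv(as.data.frame(x)[, c("id", "frame", "x", "y")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
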