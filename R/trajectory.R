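#' Derive instantaneous speed along a trajectory
#'
#' Speed at sample i is the Euclidean step from the previous sample divided by
#' the time step; the first sample copies the second so the output has no
#' leading `NA`. An optional centred moving average smooths the result.
#'
#' @param trajectory A data frame with columns `t` (s, strictly increasing)
#'   and `x`, `y` (cm).
#' @param smooth_window_s Width (s) of the centred moving-average smoother;
#'   `0` disables smoothing. Default 0.5 s, matching the spatial
#'   down-sampling resolution.
#' @return The input as a tibble with a `speed` column (cm/s) added/replaced.
#' @examples
#' traj <- tibble::tibble(t = 0:4, x = c(0, 1, 2, 3, 4), y = 0)
#' compute_speed(traj, smooth_window_s = 0)$speed
#' @export
compute_speed <- function(trajectory, smooth_window_s = 0.5) {
  trajectory <- tibble::as_tibble(trajectory)
  stopifnot(nrow(trajectory) >= 2)
  dt <- diff(trajectory$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing", call. = FALSE)
  step <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  speed <- c(NA_real_, step / dt)
  speed[1] <- speed[2]
  if (smooth_window_s > 0) {
    dt_med <- stats::median(dt)
    k <- max(1L, round(smooth_window_s / dt_med))
    if (k > 1) speed <- moving_average(speed, k)
  }
  trajectory$speed <- speed
  trajectory
}

# centred moving average with shrinking window at the edges
moving_average <- function(x, k) {
  half <- k %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Simulate open-field exploration as a smooth random walk
#'
#' Velocity follows a mean-reverting (Ornstein-Uhlenbeck) process in each
#' coordinate; the integrated position is reflected at the arena walls so all
#' samples stay in bounds. With the default parameters the animal moves at a
#' mean speed of roughly 6 cm/s with ~1 s velocity persistence, a plausible
#' mouse open-field exploration regime.
#'
#' @param arena An [arena_config()].
#' @param meta A [recording_meta()]; `fps * duration_s` samples are produced.
#' @param mobility Named list: `tau_s` velocity correlation time (s),
#'   `speed_sd_cm_s` stationary per-axis velocity standard deviation (cm/s).
#' @param seed Integer seed; identical seeds give identical trajectories.
#' @return A trajectory tibble with `t`, `x`, `y`, `speed`.
#' @export
simulate_trajectory <- function(arena, meta,
                                mobility = list(tau_s = 1, speed_sd_cm_s = 4.8),
                                seed = 1L) {
  mobility <- utils::modifyList(list(tau_s = 1, speed_sd_cm_s = 4.8), mobility)
  if (mobility$tau_s <= 0 || mobility$speed_sd_cm_s <= 0) {
    stop("mobility parameters must be positive", call. = FALSE)
  }
  n <- round(meta$fps * meta$duration_s)
  dt <- 1 / meta$fps
  set.seed(as.integer(seed))
  a <- exp(-dt / mobility$tau_s)
  b <- mobility$speed_sd_cm_s * sqrt(1 - a^2)
  vx <- numeric(n); vy <- numeric(n)
  vx[1] <- stats::rnorm(1, 0, mobility$speed_sd_cm_s)
  vy[1] <- stats::rnorm(1, 0, mobility$speed_sd_cm_s)
  ex <- stats::rnorm(n - 1); ey <- stats::rnorm(n - 1)
  for (i in seq_len(n - 1)) {
    vx[i + 1] <- a * vx[i] + b * ex[i]
    vy[i + 1] <- a * vy[i] + b * ey[i]
  }
  x <- reflect_into(arena$width_cm / 2 + cumsum(vx * dt), arena$width_cm)
  y <- reflect_into(arena$height_cm / 2 + cumsum(vy * dt), arena$height_cm)
  traj <- tibble::tibble(t = (seq_len(n) - 1) * dt, x = x, y = y)
  compute_speed(traj)
}

# fold an unbounded coordinate into [0, w] by reflection at both walls
reflect_into <- function(x, w) {
  x <- x %% (2 * w)
  ifelse(x > w, 2 * w - x, x)
}
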