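#' Score object exploration from a trajectory
#'
#' A trajectory sample counts as exploring object k when the tracked point
#' lies within `object_radius_cm` of the object's position. Each sample
#' contributes its dwell time (the interval to the next sample; the last
#' sample contributes the median interval), and per-object exploration time
#' is expressed as a percentage of the total tracked session time.
#'
#' With `exclude_immobile = TRUE` the denominator (and the dwell sums) drop
#' samples slower than `immobility_speed_cm_s`, an alternative reading of
#' "total exploration time" that discounts immobility bouts.
#'
#' @param trajectory Trajectory tibble with `t`, `x`, `y` (and `speed` if
#'   `exclude_immobile` is used; computed on the fly otherwise).
#' @param arena An [arena_config()] with at least one object.
#' @param exclude_immobile Drop immobile samples from scoring (default FALSE).
#' @param immobility_speed_cm_s Speed cutoff (cm/s) for immobility.
#' @return A tibble with one row per object: `object_id`,
#'   `exploration_time_s`, `total_time_s`, `percent_of_total`.
#' @export
score_object_exploration <- function(trajectory, arena,
                                     exclude_immobile = FALSE,
                                     immobility_speed_cm_s = 2) {
  trajectory <- tibble::as_tibble(trajectory)
  if (nrow(trajectory) == 0) stop("empty trajectory", call. = FALSE)
  if (nrow(arena$objects) == 0) stop("arena has no objects", call. = FALSE)
  dt <- diff(trajectory$t)
  dwell <- c(dt, stats::median(dt))
  keep <- rep(TRUE, nrow(trajectory))
  if (exclude_immobile) {
    if (is.null(trajectory[["speed"]])) {
      trajectory <- compute_speed(trajectory)
    }
    keep <- trajectory$speed >= immobility_speed_cm_s
  }
  total <- sum(dwell[keep])
  purrr::pmap_dfr(arena$objects, function(object_id, x, y) {
    near <- sqrt((trajectory$x - x)^2 + (trajectory$y - y)^2) <=
      arena$object_radius_cm
    et <- sum(dwell[near & keep])
    tibble::tibble(object_id = object_id, exploration_time_s = et,
                   total_time_s = total,
                   percent_of_total = 100 * et / total)
  })
}

#' Object discrimination index
#'
#' `DI = (t_displaced - t_stationary) / (t_displaced + t_stationary)`, the
#' normalised preference for the displaced over the stationary object,
#' bounded in \[-1, 1\]. Positive values index item-place memory (preference
#' for the spatially novel object).
#'
#' @param t_displaced,t_stationary Exploration times (s); vectorised.
#' @return Numeric vector in \[-1, 1\]; `NA` (with a warning) where both
#'   times are zero.
#' @examples
#' discrimination_index(6, 4) # 0.2
#' @export
discrimination_index <- function(t_displaced, t_stationary) {
  tot <- t_displaced + t_stationary
  out <- (t_displaced - t_stationary) / tot
  if (any(tot == 0)) {
    warning("discrimination index undefined when both times are zero",
            call. = FALSE)
    out[tot == 0] <- NA_real_
  }
  out
}
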