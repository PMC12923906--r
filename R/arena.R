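#' Arena geometry and spatial binning
#'
#' Describes the open-field arena: its extent in cm, the positions of any
#' objects placed in it, the radius around an object that counts as the
#' exploration zone, and the spatial bin grid used for rate maps.
#'
#' The coordinate frame has its origin at the lower-left corner of the arena,
#' x increasing rightwards and y upwards, in cm. Bin `(i, j)` (1-based) covers
#' the half-open square `[(i-1)*w, i*w) x [(j-1)*h, j*h)`; the top and right
#' arena edges are closed so that every in-arena point falls in exactly one
#' bin.
#'
#' @param width_cm,height_cm Arena extent in cm (default 40 x 40).
#' @param objects A data frame with columns `object_id`, `x`, `y` (cm), or
#'   `NULL` for an empty arena. A bare list/matrix of xy pairs is accepted and
#'   labelled `obj1`, `obj2`, ...
#' @param object_radius_cm Radius (cm) of the exploration zone around each
#'   object (default 2).
#' @param n_bins_x,n_bins_y Number of spatial bins along each axis
#'   (default 10 x 10, i.e. ~4 cm bins at the default extent).
#' @return An object of class `arena_config`.
#' @examples
#' arena_config(objects = data.frame(object_id = c("left", "right"),
#'                                   x = c(12, 28), y = c(20, 20)))
#' @export
arena_config <- function(width_cm = 40, height_cm = 40, objects = NULL,
                         object_radius_cm = 2, n_bins_x = 10, n_bins_y = 10) {
  stopifnot(width_cm > 0, height_cm > 0, object_radius_cm > 0,
            n_bins_x >= 1, n_bins_y >= 1)
  objects <- normalize_objects(objects)
  if (nrow(objects) > 0 &&
      any(objects$x < 0 | objects$x > width_cm |
          objects$y < 0 | objects$y > height_cm)) {
    stop("all objects must lie inside the arena", call. = FALSE)
  }
  structure(
    list(width_cm = width_cm, height_cm = height_cm, objects = objects,
         object_radius_cm = object_radius_cm,
         n_bins_x = as.integer(n_bins_x), n_bins_y = as.integer(n_bins_y)),
    class = "arena_config"
  )
}

normalize_objects <- function(objects) {
  if (is.null(objects) || (is.data.frame(objects) && nrow(objects) == 0)) {
    return(tibble::tibble(object_id = character(), x = numeric(), y = numeric()))
  }
  if (is.matrix(objects)) {
    objects <- tibble::tibble(x = objects[, 1], y = objects[, 2])
  } else if (is.list(objects) && !is.data.frame(objects)) {
    objects <- tibble::tibble(x = vapply(objects, `[`, 0, 1),
                              y = vapply(objects, `[`, 0, 2))
  }
  objects <- tibble::as_tibble(objects)
  if (!all(c("x", "y") %in% names(objects))) {
    stop("objects must have x and y columns", call. = FALSE)
  }
  if (is.null(objects[["object_id"]])) {
    objects$object_id <- paste0("obj", seq_len(nrow(objects)))
  }
  objects$object_id <- as.character(objects$object_id)
  objects[, c("object_id", "x", "y")]
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %g x %g cm, %d x %d bins, %d object(s)\n",
              x$width_cm, x$height_cm, x$n_bins_x, x$n_bins_y,
              nrow(x$objects)))
  invisible(x)
}

#' Spatial bin index of xy positions
#'
#' Maps positions (cm) to 1-based bin indices along each axis. Binning is
#' half-open with the top/right arena edge closed, so a point exactly on the
#' far edge falls in the last bin. Out-of-arena points return `NA`.
#'
#' @param x,y Numeric vectors of positions in cm.
#' @param arena An [arena_config()].
#' @return A tibble with integer columns `bin_x`, `bin_y` and `bin`
#'   (linear index, column-major: `bin = bin_x + (bin_y - 1) * n_bins_x`).
#' @export
bin_xy <- function(x, y, arena) {
  wx <- arena$width_cm / arena$n_bins_x
  wy <- arena$height_cm / arena$n_bins_y
  bx <- pmin(floor(x / wx) + 1L, arena$n_bins_x)
  by <- pmin(floor(y / wy) + 1L, arena$n_bins_y)
  bad <- x < 0 | x > arena$width_cm | y < 0 | y > arena$height_cm
  bx[bad] <- NA_integer_
  by[bad] <- NA_integer_
  tibble::tibble(bin_x = as.integer(bx), bin_y = as.integer(by),
                 bin = as.integer(bx + (by - 1L) * arena$n_bins_x))
}

#' Centres of the spatial bins
#'
#' @param arena An [arena_config()].
#' @return A tibble with `bin_x`, `bin_y`, `x`, `y` (bin centres, cm) for all
#'   `n_bins_x * n_bins_y` bins.
#' @export
bin_centers <- function(arena) {
  wx <- arena$width_cm / arena$n_bins_x
  wy <- arena$height_cm / arena$n_bins_y
  grid <- expand.grid(bin_x = seq_len(arena$n_bins_x),
                      bin_y = seq_len(arena$n_bins_y))
  tibble::tibble(bin_x = as.integer(grid$bin_x), bin_y = as.integer(grid$bin_y),
                 x = (grid$bin_x - 0.5) * wx, y = (grid$bin_y - 0.5) * wy)
}

bin_area_cm2 <- function(arena) {
  (arena$width_cm / arena$n_bins_x) * (arena$height_cm / arena$n_bins_y)
}

#' Recording metadata for one session
#'
#' @param session_label One of `"HA"`, `"S1"`, `"S2"`, `"S3"` (habituation and
#'   the three object sessions).
#' @param fps Imaging frame rate, frames/s (default 20).
#' @param duration_s Session duration in seconds (default 600, i.e. 10 min).
#' @param animal_id,group_label Identifiers carried through all outputs.
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(session_label, fps = 20, duration_s = 600,
                           animal_id = "animal1", group_label = "vehicle") {
  session_label <- match.arg(session_label, session_labels())
  stopifnot(fps > 0, duration_s > 0)
  structure(
    list(session_label = session_label, fps = fps, duration_s = duration_s,
         animal_id = as.character(animal_id),
         group_label = as.character(group_label)),
    class = "recording_meta"
  )
}

#' Session labels of the item-place design
#'
#' Habituation (`HA`, object-free baseline) followed by three 10-min object
#' sessions `S1`, `S2`, `S3`.
#' @return Character vector of the four labels in temporal order.
#' @export
session_labels <- function() c("HA", "S1", "S2", "S3")

#' Analysis configuration
#'
#' Collects every numeric parameter used downstream, with the pipeline
#' defaults: population bursts are runs of the population z-score above
#' `z_threshold` lasting at least `min_duration_s`; spatial analysis
#' down-samples the trajectory to `downsample_dt_s` windows, smooths rate maps
#' with an isotropic Gaussian of `gaussian_sigma_bins`, uses `n_shuffles`
#' circular shuffles at level `alpha` with a minimum of `min_events` events,
#' extracts fields at `field_threshold_frac` of the peak rate and pads object
#' bins by `object_pad_bins`; network edges require Bonferroni-adjusted
#' two-sided Spearman p below `edge_alpha` with positive correlation.
#'
#' @param burst,spatial,network Named lists overriding individual defaults.
#' @param seed Integer seed that makes the full pipeline deterministic.
#' @return A nested list of class `analysis_config`.
#' @export
analysis_config <- function(burst = list(), spatial = list(), network = list(),
                            seed = 1L) {
  cfg <- list(
    burst = utils::modifyList(
      list(z_threshold = 2, min_duration_s = 0.05), burst),
    spatial = utils::modifyList(
      list(downsample_dt_s = 0.5, gaussian_sigma_bins = 1.0, n_shuffles = 500L,
           alpha = 0.05, min_events = 20L, field_threshold_frac = 0.2,
           object_pad_bins = 2L, min_shift_s = 10), spatial),
    network = utils::modifyList(
      list(edge_alpha = 0.001, correction = "bonferroni",
           positive_only = TRUE, distance = "inverse"), network),
    seed = as.integer(seed)
  )
  stopifnot(cfg$burst$z_threshold > 0, cfg$burst$min_duration_s > 0,
            cfg$spatial$downsample_dt_s > 0, cfg$spatial$n_shuffles >= 1,
            cfg$spatial$alpha > 0, cfg$spatial$alpha < 1,
            cfg$spatial$min_events >= 0, cfg$spatial$field_threshold_frac > 0,
            cfg$network$edge_alpha > 0, cfg$network$edge_alpha < 1)
  structure(cfg, class = "analysis_config")
}
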