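#' Bundle one session's data products
#'
#' A session dataset collects everything recorded for one animal in one
#' session downstream of cell extraction: recording metadata, the animal's
#' trajectory, the ΔF/F trace matrix, the deconvolved event trains, and the
#' arena/object configuration in force during that session.
#'
#' @param meta A [recording_meta()].
#' @param trajectory A tibble with `t`, `x`, `y` (and optionally `speed`).
#' @param traces A numeric matrix, cells x frames, with rownames = cell ids.
#' @param events A tibble with columns `cell_id`, `time_s` and optionally
#'   `amplitude`; one row per deconvolved calcium transient.
#' @param arena An [arena_config()].
#' @return An object of class `session_dataset`.
#' @export
session_dataset <- function(meta, trajectory, traces, events, arena) {
  events <- tibble::as_tibble(events)
  if (is.null(events[["amplitude"]])) events$amplitude <- 1
  events$cell_id <- as.character(events$cell_id)
  x <- structure(
    list(meta = meta, trajectory = tibble::as_tibble(trajectory),
         traces = traces, events = events, arena = arena),
    class = "session_dataset"
  )
  validate_session(x)
}

validate_session <- function(x) {
  traj <- x$trajectory
  stopifnot(all(c("t", "x", "y") %in% names(traj)))
  if (nrow(traj) < 2) stop("trajectory must have >= 2 samples", call. = FALSE)
  if (anyNA(traj$x) || anyNA(traj$y) || anyNA(traj$t)) {
    stop("trajectory contains NA positions or times", call. = FALSE)
  }
  if (any(traj$t < 0)) stop("negative trajectory times", call. = FALSE)
  if (any(diff(traj$t) <= 0)) {
    stop("trajectory timestamps must be strictly increasing", call. = FALSE)
  }
  ar <- x$arena
  if (any(traj$x < 0 | traj$x > ar$width_cm |
          traj$y < 0 | traj$y > ar$height_cm)) {
    stop("trajectory leaves the arena bounds", call. = FALSE)
  }
  if (!is.matrix(x$traces) || !is.numeric(x$traces)) {
    stop("traces must be a numeric matrix (cells x frames)", call. = FALSE)
  }
  if (any(!is.finite(x$traces))) stop("non-finite trace values", call. = FALSE)
  if (is.null(rownames(x$traces))) {
    stop("trace matrix must carry cell ids as rownames", call. = FALSE)
  }
  dur <- x$meta$duration_s
  frame <- 1 / x$meta$fps
  if (abs(ncol(x$traces) * frame - dur) > frame + 1e-9) {
    stop(sprintf("trace duration (%.2f s) does not match session duration (%.2f s)",
                 ncol(x$traces) * frame, dur), call. = FALSE)
  }
  if (abs(max(traj$t) + frame - dur) > max(frame, diff(range(traj$t)) / nrow(traj)) + 1e-9 &&
      abs(max(traj$t) - dur) > frame + 1e-9) {
    stop(sprintf("trajectory span (%.2f s) does not match session duration (%.2f s)",
                 max(traj$t), dur), call. = FALSE)
  }
  ev <- x$events
  if (nrow(ev) > 0) {
    if (anyNA(ev$time_s) || any(ev$time_s < 0) || any(ev$time_s > dur)) {
      stop("event times must lie within [0, duration_s]", call. = FALSE)
    }
    by_cell <- split(ev$time_s, ev$cell_id)
    if (any(vapply(by_cell, is.unsorted, TRUE))) {
      stop("event times must be sorted ascending within each cell", call. = FALSE)
    }
    if (!all(ev$cell_id %in% rownames(x$traces))) {
      stop("event cell ids must appear in the trace matrix", call. = FALSE)
    }
  }
  x
}

#' @export
print.session_dataset <- function(x, ...) {
  cat(sprintf("<session_dataset> %s %s [%s]: %d cells, %d frames @ %g fps, %d events\n",
              x$meta$animal_id, x$meta$session_label, x$meta$group_label,
              nrow(x$traces), ncol(x$traces), x$meta$fps, nrow(x$events)))
  invisible(x)
}

#' Event trains as a named list
#'
#' @param session A [session_dataset()].
#' @return Named list (one element per cell in trace order) of sorted event
#'   time vectors; cells without events get `numeric(0)`.
#' @export
event_trains <- function(session) {
  ids <- rownames(session$traces)
  by_cell <- split(session$events$time_s, session$events$cell_id)
  out <- lapply(ids, function(id) as.numeric(by_cell[[id]]))
  names(out) <- ids
  out
}

# ---- on-disk layout -------------------------------------------------------
# A session directory holds manifest.yaml (meta + arena + file names),
# trajectory.csv (t,x,y), events.csv (cell_id,time_s,amplitude) and
# traces.csv (wide: cell_id then one column per frame).

#' Write a session dataset to a directory
#'
#' Writes `manifest.yaml`, `trajectory.csv`, `events.csv` and `traces.csv`
#' (wide CSV, one row per cell). All numeric values round-trip exactly.
#'
#' @param session A [session_dataset()].
#' @param dir Output directory (created if necessary).
#' @return The path to the manifest, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(session$trajectory[, c("t", "x", "y")],
                   file.path(dir, "trajectory.csv"), progress = FALSE)
  readr::write_csv(session$events[, c("cell_id", "time_s", "amplitude")],
                   file.path(dir, "events.csv"), progress = FALSE)
  tr <- tibble::as_tibble(session$traces, .name_repair = ~ paste0("f", seq_along(.x)))
  tr <- dplyr::bind_cols(tibble::tibble(cell_id = rownames(session$traces)), tr)
  readr::write_csv(tr, file.path(dir, "traces.csv"), progress = FALSE)
  manifest <- list(
    meta = unclass(session$meta),
    arena = c(unclass(session$arena)[c("width_cm", "height_cm",
                                       "object_radius_cm")],
              list(n_bins_x = session$arena$n_bins_x,
                   n_bins_y = session$arena$n_bins_y,
                   objects = lapply(seq_len(nrow(session$arena$objects)), function(i)
                     as.list(session$arena$objects[i, ])))),
    files = list(trajectory = "trajectory.csv", events = "events.csv",
                 traces = "traces.csv")
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Read a session dataset from a manifest
#'
#' Reads the YAML manifest written by [write_session()] plus the CSV files it
#' references, validating units, monotone timestamps and matching durations.
#'
#' @param manifest_path Path to `manifest.yaml` (or to the session directory).
#' @return A validated [session_dataset()].
#' @export
read_session <- function(manifest_path) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.yaml")
  }
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- yaml::read_yaml(manifest_path)
  dir <- dirname(manifest_path)
  need <- file.path(dir, unlist(m$files))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing session files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  meta <- recording_meta(session_label = m$meta$session_label,
                         fps = m$meta$fps, duration_s = m$meta$duration_s,
                         animal_id = m$meta$animal_id,
                         group_label = m$meta$group_label)
  objects <- if (length(m$arena$objects)) {
    dplyr::bind_rows(lapply(m$arena$objects, tibble::as_tibble))
  } else NULL
  arena <- arena_config(width_cm = m$arena$width_cm,
                        height_cm = m$arena$height_cm,
                        objects = objects,
                        object_radius_cm = m$arena$object_radius_cm,
                        n_bins_x = m$arena$n_bins_x, n_bins_y = m$arena$n_bins_y)
  traj <- readr::read_csv(file.path(dir, m$files$trajectory),
                          col_types = "ddd", progress = FALSE)
  events <- readr::read_csv(file.path(dir, m$files$events),
                            col_types = "cdd", progress = FALSE)
  tr <- readr::read_csv(file.path(dir, m$files$traces),
                        col_types = readr::cols(
                          cell_id = readr::col_character(),
                          .default = readr::col_double()),
                        progress = FALSE)
  traces <- as.matrix(tr[, -1, drop = FALSE])
  dimnames(traces) <- list(tr$cell_id, NULL)
  session_dataset(meta, traj, traces, events, arena)
}
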