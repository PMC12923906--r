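#' Longitudinal cell-registration map
#'
#' Records, for every globally registered cell, its per-session cell index (or
#' absence) across the four sessions. Habituation (`HA`) is the reference
#' session of the registration. The map is consumed as produced by a
#' footprint-registration tool; the registration algorithm itself is out of
#' scope.
#'
#' @param table A data frame with column `global_id` plus one column per
#'   session label (`HA`, `S1`, `S2`, `S3`); entries are per-session cell
#'   indices or `NA` for cells not detected in that session.
#' @return An object of class `registration_map` (a tibble).
#' @export
registration_map <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("global_id", session_labels())
  if (!all(need %in% names(table))) {
    stop("registration table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  table$global_id <- as.character(table$global_id)
  if (anyDuplicated(table$global_id)) {
    stop("duplicate global cell ids", call. = FALSE)
  }
  for (s in session_labels()) {
    idx <- table[[s]]
    dup <- idx[!is.na(idx)][duplicated(idx[!is.na(idx)])]
    if (length(dup)) {
      stop(sprintf("session %s maps index %s to more than one global cell",
                   s, paste(unique(dup), collapse = ", ")), call. = FALSE)
    }
  }
  structure(table[, need], class = c("registration_map", class(table)))
}

#' Read / write a registration map
#'
#' CSV with columns `global_id,HA,S1,S2,S3`; absence is encoded as the
#' literal string `NA` (the common registration-export convention).
#'
#' @param path CSV file path.
#' @return [read_registration()] returns a `registration_map`;
#'   [write_registration()] returns the path invisibly.
#' @export
read_registration <- function(path) {
  if (!file.exists(path)) stop("registration file not found: ", path,
                               call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    global_id = readr::col_character(), .default = readr::col_integer()),
    na = "NA", progress = FALSE)
  registration_map(tab)
}

#' @rdname read_registration
#' @param regmap A `registration_map`.
#' @export
write_registration <- function(regmap, path) {
  readr::write_csv(tibble::as_tibble(regmap), path, na = "NA",
                   progress = FALSE)
  invisible(path)
}

#' Active cells of a session
#'
#' A cell is active in a session if it has an entry in the session's
#' registration column and, when event counts are supplied, at least
#' `min_events` recorded events in that session.
#'
#' @param regmap A [registration_map()].
#' @param session A session label.
#' @param event_counts Optional named vector of per-global-id event counts
#'   for this session; when given, cells below `min_events` are dropped.
#' @param min_events Minimum event count for activity (default 1).
#' @return Character vector of active global cell ids.
#' @export
active_cells <- function(regmap, session, event_counts = NULL, min_events = 1L) {
  session <- match.arg(session, session_labels())
  ids <- regmap$global_id[!is.na(regmap[[session]])]
  if (!is.null(event_counts)) {
    counts <- event_counts[ids]
    counts[is.na(counts)] <- 0
    ids <- ids[counts >= min_events]
  }
  ids
}

#' Session ensemble size normalised to habituation
#'
#' The active-cell count of a session expressed as a percentage of the
#' habituation-session count (may exceed 100).
#'
#' @inheritParams active_cells
#' @return A single percentage.
#' @export
active_percent <- function(regmap, session, event_counts = NULL,
                           min_events = 1L) {
  n_ha <- length(active_cells(regmap, "HA", event_counts, min_events))
  if (n_ha == 0) stop("no active cells in the habituation session",
                      call. = FALSE)
  100 * length(active_cells(regmap, session, event_counts, min_events)) / n_ha
}

#' Reactivation between two sessions
#'
#' Percentage of the earlier session's active cells that are active again in
#' the later session (the earlier session is the denominator).
#'
#' @inheritParams active_cells
#' @param earlier,later Session labels of the pair.
#' @param event_counts Optional named list of per-session event-count vectors.
#' @return A single percentage in \[0, 100\].
#' @export
reactivation_percent <- function(regmap, earlier, later, event_counts = NULL,
                                 min_events = 1L) {
  a <- active_cells(regmap, earlier, event_counts[[earlier]], min_events)
  b <- active_cells(regmap, later, event_counts[[later]], min_events)
  if (length(a) == 0) stop("earlier session has no active cells", call. = FALSE)
  100 * length(intersect(a, b)) / length(a)
}

#' Per-session and pairwise ensemble statistics
#'
#' Computes active-cell counts, counts normalised to habituation, and the
#' reactivation percentages for the successive pairs HA->S1, S1->S2, S2->S3.
#'
#' @inheritParams reactivation_percent
#' @return A tidy tibble with columns `scope` (`"session"`/`"pair"`), `label`,
#'   `metric`, `value`.
#' @export
ensemble_summary <- function(regmap, event_counts = NULL, min_events = 1L) {
  sessions <- session_labels()
  counts <- vapply(sessions, function(s)
    length(active_cells(regmap, s, event_counts[[s]], min_events)), 0L)
  per_session <- tibble::tibble(
    scope = "session", label = rep(sessions, 2),
    metric = rep(c("active_count", "active_percent_of_HA"), each = 4),
    value = c(as.numeric(counts), as.numeric(100 * counts / counts[["HA"]])))
  pairs <- list(c("HA", "S1"), c("S1", "S2"), c("S2", "S3"))
  per_pair <- tibble::tibble(
    scope = "pair",
    label = vapply(pairs, paste, "", collapse = "->"),
    metric = "reactivation_percent",
    value = vapply(pairs, function(p)
      reactivation_percent(regmap, p[1], p[2], event_counts, min_events), 0))
  dplyr::bind_rows(per_session, per_pair)
}
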