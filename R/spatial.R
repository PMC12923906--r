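#' Circular-shuffle significance of spatial information
#'
#' The null distribution is obtained by rotating the entire event train in
#' time by a random offset (uniform on `[min_shift_s, T - min_shift_s]`,
#' modulo the session duration) while the behavioural record stays fixed, and
#' recomputing the information score; the empirical p-value is the proportion
#' of shuffled scores that equal or exceed the observed score.
#'
#' @param trajectory Trajectory tibble.
#' @param events Event times (s) of one cell (vector or tibble with `time_s`).
#' @param arena An [arena_config()].
#' @param n_shuffles Number of shuffles (default 500).
#' @param seed Integer seed (reproducible null).
#' @param dt Spatial down-sampling resolution (s).
#' @param min_shift_s Minimum rotation (s, default 10) so shuffles never sit
#'   near the identity.
#' @return A list: `p_value`, `info_observed` (bits/event),
#'   `info_shuffled` (vector), `n_events_used`.
#' @export
shuffle_p_value <- function(trajectory, events, arena, n_shuffles = 500,
                            seed = 1L, dt = 0.5, min_shift_s = 10) {
  if (is.data.frame(events)) events <- events$time_s
  if (length(events) < 1) stop("no events to test", call. = FALSE)
  wb <- window_bins(trajectory, arena, dt)
  dur <- wb$duration_s
  if (dur <= 2 * min_shift_s) {
    stop("session too short for the minimum circular shift", call. = FALSE)
  }
  n_bins <- arena$n_bins_x * arena$n_bins_y
  occ <- tabulate(wb$win_bin[!is.na(wb$win_bin)], n_bins) * dt

  bin_of_times <- function(tt) {
    w <- pmin(floor(tt / dt) + 1L, wb$n_win)
    b <- wb$win_bin[w]
    b[!is.na(b)]
  }
  obs_bins <- bin_of_times(events)
  if (length(obs_bins) == 0) stop("no events overlap tracked windows",
                                  call. = FALSE)
  info_obs <- info_from_counts(tabulate(obs_bins, n_bins), occ)

  set.seed(as.integer(seed))
  offsets <- stats::runif(n_shuffles, min_shift_s, dur - min_shift_s)
  info_shuf <- vapply(offsets, function(off) {
    b <- bin_of_times((events + off) %% dur)
    if (length(b) == 0) return(0)
    info_from_counts(tabulate(b, n_bins), occ)
  }, 0)
  list(p_value = mean(info_shuf >= info_obs),
       info_observed = info_obs, info_shuffled = info_shuf,
       n_events_used = length(obs_bins))
}

#' Place-cell-like classification
#'
#' A cell is place-cell-like only if its spatial information is significant
#' under the circular-shuffle null (`p < alpha`, strict) AND it fired at
#' least `min_events` events during the recording (adequate-sampling
#' criterion).
#'
#' @param p_value Empirical shuffle p-value(s).
#' @param n_events Event count(s) during the recording.
#' @param alpha Significance level (default 0.05).
#' @param min_events Minimum event count (default 20).
#' @return Logical vector.
#' @export
classify_place_cell <- function(p_value, n_events, alpha = 0.05,
                                min_events = 20) {
  (p_value < alpha) & (n_events >= min_events)
}

#' Extract place fields from a smoothed rate map
#'
#' Bins at or above `threshold_frac` of the map's peak rate are kept and
#' partitioned into contiguous regions (4-connectivity); each region is a
#' field with an (occupancy-unweighted) centroid at the mean of its bin
#' centres and a size of bin-count times bin area. Multiple fields are
#' allowed.
#'
#' @param rate A rate-map matrix, or a [smooth_rate_map()]ed bundle (its
#'   `smoothed_rate` is used).
#' @param arena An [arena_config()] (taken from the bundle when omitted).
#' @param threshold_frac Fraction of the peak rate (default 0.2).
#' @return A tibble, one row per field: `field_id`, `n_bins`, `size_cm2`,
#'   `centroid_x`, `centroid_y`, `bins` (list column of `bin_x`, `bin_y`
#'   tibbles).
#' @export
extract_fields <- function(rate, arena = NULL, threshold_frac = 0.2) {
  if (inherits(rate, "ratemap_bundle")) {
    if (is.null(rate$smoothed_rate)) stop("bundle has no smoothed rate map",
                                          call. = FALSE)
    arena <- rate$arena
    rate <- rate$smoothed_rate
  }
  stopifnot(!is.null(arena))
  vals <- rate[!is.na(rate)]
  if (length(vals) == 0 || max(vals) <= 0) {
    stop("rate map has no positive peak", call. = FALSE)
  }
  thr <- threshold_frac * max(vals)
  supra <- !is.na(rate) & rate >= thr
  labels <- label_components(supra)
  nf <- max(labels)
  if (nf == 0) return(empty_fields())
  centers <- bin_centers(arena)
  area <- bin_area_cm2(arena)
  purrr::map_dfr(seq_len(nf), function(f) {
    idx <- which(labels == f, arr.ind = TRUE)
    bins <- tibble::tibble(bin_x = as.integer(idx[, 1]),
                           bin_y = as.integer(idx[, 2]))
    ctr <- dplyr::inner_join(bins, centers, by = c("bin_x", "bin_y"))
    tibble::tibble(field_id = f, n_bins = nrow(bins),
                   size_cm2 = nrow(bins) * area,
                   centroid_x = mean(ctr$x), centroid_y = mean(ctr$y),
                   bins = list(bins))
  })
}

empty_fields <- function() {
  tibble::tibble(field_id = integer(), n_bins = integer(),
                 size_cm2 = numeric(), centroid_x = numeric(),
                 centroid_y = numeric(), bins = list())
}

# 4-connected component labelling of a logical matrix (flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    nr <- nrow(mask)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      i <- (v - 1L) %% nr + 1L
      j <- (v - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1 && nb[1] <= nr && nb[2] >= 1 && nb[2] <= ncol(mask)) {
          w <- nb[1] + (nb[2] - 1L) * nr
          if (mask[w] && lab[w] == 0L) {
            lab[w] <- cur
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  lab
}

#' Spatial coherence of a rate map
#'
#' Each visited bin's raw rate is compared with the box-car average of its
#' visited 3x3 neighbours (centre excluded); the Pearson correlation between
#' the two vectors over all visited bins with at least one visited neighbour
#' is Fisher z-transformed. Higher values mean more spatially contiguous
#' firing.
#'
#' @param bundle A [bin_session()] result.
#' @return Fisher-z coherence (atanh of r, clipped to finite values).
#' @export
spatial_coherence <- function(bundle) {
  vis <- bundle$visited
  idx <- which(vis, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("need at least 3 visited bins", call. = FALSE)
  raw <- bundle$raw_rate
  nr <- nrow(raw); nc <- ncol(raw)
  box <- rep(NA_real_, nrow(idx))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ni <- max(1, i - 1):min(nr, i + 1)
    nj <- max(1, j - 1):min(nc, j + 1)
    nbr <- expand.grid(ni, nj)
    nbr <- nbr[!(nbr[, 1] == i & nbr[, 2] == j), , drop = FALSE]
    v <- vis[cbind(nbr[, 1], nbr[, 2])]
    if (any(v)) box[k] <- mean(raw[cbind(nbr[v, 1], nbr[v, 2])])
  }
  ok <- !is.na(box)
  a <- raw[idx][ok]; b <- box[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("coherence undefined: constant rate map", call. = FALSE)
  }
  r <- stats::cor(a, b)
  lim <- 1 - 1e-12
  atanh(pmin(pmax(r, -lim), lim))
}

#' Object-vicinity bin mask
#'
#' Marks, for each object, the square neighbourhood extending `pad` bins
#' beyond the object's centroid bin in every direction (5x5 bins at the
#' default pad of 2), clipped at the arena edges; the mask is the union over
#' objects.
#'
#' @param arena An [arena_config()].
#' @param pad Padding in bins (default 2).
#' @return Logical matrix `n_bins_x` x `n_bins_y`.
#' @export
object_mask <- function(arena, pad = 2) {
  mask <- matrix(FALSE, arena$n_bins_x, arena$n_bins_y)
  if (nrow(arena$objects) == 0) return(mask)
  ob <- bin_xy(arena$objects$x, arena$objects$y, arena)
  for (k in seq_len(nrow(ob))) {
    xi <- max(1, ob$bin_x[k] - pad):min(arena$n_bins_x, ob$bin_x[k] + pad)
    yi <- max(1, ob$bin_y[k] - pad):min(arena$n_bins_y, ob$bin_y[k] + pad)
    mask[xi, yi] <- TRUE
  }
  mask
}

#' Overlap of a cell's place fields with the object vicinity
#'
#' Fraction of the cell's field bins that fall inside the padded object mask,
#' from 0 (no overlap) to 1 (fields entirely inside object zones). By default
#' all field bins of the cell are pooled; `method = "per_field_mean"` instead
#' averages the per-field overlap fractions.
#'
#' @param fields A field tibble from [extract_fields()].
#' @param mask Logical bin mask from [object_mask()].
#' @param method `"pooled"` (default) or `"per_field_mean"`.
#' @return A fraction in \[0, 1\].
#' @export
object_score <- function(fields, mask, method = c("pooled", "per_field_mean")) {
  method <- match.arg(method)
  if (nrow(fields) == 0) stop("cell has no fields", call. = FALSE)
  per_field <- vapply(fields$bins, function(b)
    mean(mask[cbind(b$bin_x, b$bin_y)]), 0)
  if (method == "per_field_mean") return(mean(per_field))
  sum(per_field * fields$n_bins) / sum(fields$n_bins)
}

#' Full spatial analysis of every cell in a session
#'
#' For each cell: events are binned on the down-sampled trajectory, Skaggs
#' information and its circular-shuffle p-value computed, the place-cell-like
#' flag assigned (`p < alpha` and `>= min_events` events), fields extracted
#' from the Gaussian-smoothed map, spatial coherence Fisher-z computed, and —
#' when the arena contains objects — the object-vicinity overlap score of the
#' fields. Cells below `min_events` skip the shuffle test (they can never be
#' classified) but still report information and maps.
#'
#' @param session A [session_dataset()].
#' @param config An [analysis_config()]; per-cell shuffle seeds derive
#'   deterministically from `config$seed`.
#' @param keep_maps Attach each cell's `ratemap_bundle` as a list column.
#' @return A tibble, one row per cell: `cell_id`, `n_events`,
#'   `info_bits_per_event`, `p_value`, `is_place_cell_like`, `n_fields`,
#'   `total_field_size_cm2`, `coherence_z`, `object_score` (`NA` without
#'   objects or fields).
#' @export
analyze_spatial_cells <- function(session, config = analysis_config(),
                                  keep_maps = FALSE) {
  sp <- config$spatial
  arena <- session$arena
  trains <- event_trains(session)
  mask <- object_mask(arena, sp$object_pad_bins)
  has_objects <- nrow(arena$objects) > 0
  rows <- purrr::imap(trains, function(ev, id) {
    n_ev <- length(ev)
    out <- tibble::tibble(cell_id = id, n_events = n_ev,
                          info_bits_per_event = NA_real_, p_value = NA_real_,
                          is_place_cell_like = FALSE, n_fields = NA_integer_,
                          total_field_size_cm2 = NA_real_,
                          coherence_z = NA_real_, object_score = NA_real_)
    if (n_ev == 0) return(out)
    bundle <- bin_session(session$trajectory, ev, arena, dt = sp$downsample_dt_s)
    bundle <- smooth_rate_map(bundle, sigma = sp$gaussian_sigma_bins)
    out$info_bits_per_event <- skaggs_information(bundle)
    if (n_ev >= sp$min_events) {
      shuf <- shuffle_p_value(session$trajectory, ev, arena,
                              n_shuffles = sp$n_shuffles,
                              seed = cell_seed(config$seed, id),
                              dt = sp$downsample_dt_s,
                              min_shift_s = sp$min_shift_s)
      out$p_value <- shuf$p_value
      out$is_place_cell_like <- classify_place_cell(shuf$p_value, n_ev,
                                                    sp$alpha, sp$min_events)
    }
    fields <- tryCatch(
      extract_fields(bundle, threshold_frac = sp$field_threshold_frac),
      error = function(e) empty_fields())
    out$n_fields <- nrow(fields)
    out$total_field_size_cm2 <- if (nrow(fields)) sum(fields$size_cm2) else 0
    out$coherence_z <- tryCatch(spatial_coherence(bundle),
                                error = function(e) NA_real_)
    if (has_objects && nrow(fields) > 0) {
      out$object_score <- object_score(fields, mask)
    }
    if (keep_maps) out$ratemap <- list(bundle)
    out
  })
  dplyr::bind_rows(rows)
}

# deterministic 32-bit sub-seed per cell id
cell_seed <- function(seed, id) {
  h <- sum(utf8ToInt(as.character(id)) * seq_along(utf8ToInt(as.character(id))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
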