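#' Bin a session into occupancy and event-count maps
#'
#' The trajectory is down-sampled to `dt`-second windows (positions averaged
#' per window); every deconvolved event is assigned to the spatial bin of its
#' window's position. Occupancy time per bin is `dt` times the number of
#' windows falling in it; bins without events hold zero counts, and the
#' proportion of visited bins is recorded.
#'
#' @param trajectory Trajectory tibble with `t`, `x`, `y` covering the events.
#' @param events Numeric vector of event times (s) for one cell, or an event
#'   tibble with `time_s`.
#' @param arena An [arena_config()].
#' @param dt Down-sampling resolution in seconds (default 0.5).
#' @return An object of class `ratemap_bundle`: matrices `spike_counts`,
#'   `occupancy_s`, `visited`, `raw_rate` (events/s, `NA` where unvisited),
#'   scalars `n_events_used`, `prop_visited`, plus `arena` and `dt`.
#' @export
bin_session <- function(trajectory, events, arena, dt = 0.5) {
  if (is.data.frame(events)) events <- events$time_s
  wb <- window_bins(trajectory, arena, dt)
  n_bins <- arena$n_bins_x * arena$n_bins_y
  occ <- tabulate(wb$win_bin[!is.na(wb$win_bin)], n_bins) * dt
  if (any(events < 0 | events > wb$duration_s)) {
    stop("events outside the trajectory span", call. = FALSE)
  }
  ev_win <- pmin(floor(events / dt) + 1L, wb$n_win)
  ev_bin <- wb$win_bin[ev_win]
  if (anyNA(ev_bin)) {
    warning(sum(is.na(ev_bin)),
            " event(s) in windows without tracking samples dropped",
            call. = FALSE)
    ev_bin <- ev_bin[!is.na(ev_bin)]
  }
  counts <- tabulate(ev_bin, n_bins)
  dim(occ) <- dim(counts) <- c(arena$n_bins_x, arena$n_bins_y)
  visited <- occ > 0
  raw <- matrix(NA_real_, arena$n_bins_x, arena$n_bins_y)
  raw[visited] <- counts[visited] / occ[visited]
  structure(list(spike_counts = counts, occupancy_s = occ, visited = visited,
                 raw_rate = raw, arena = arena, dt = dt,
                 n_events_used = length(ev_bin),
                 prop_visited = mean(visited)),
            class = "ratemap_bundle")
}

# window -> spatial bin lookup shared by binning and the shuffle null:
# window w covers [(w-1)dt, w dt); its position is the mean of the trajectory
# samples inside it (NA when none fall there)
window_bins <- function(trajectory, arena, dt) {
  t_end <- max(trajectory$t)
  n_win <- max(1L, ceiling((t_end + 1e-9) / dt))
  win <- pmin(floor(trajectory$t / dt) + 1L, n_win)
  mx <- rowsum(trajectory$x, win) / tabulate(win, n_win)[sort(unique(win))]
  my <- rowsum(trajectory$y, win) / tabulate(win, n_win)[sort(unique(win))]
  wx <- rep(NA_real_, n_win); wy <- rep(NA_real_, n_win)
  present <- sort(unique(win))
  wx[present] <- mx; wy[present] <- my
  win_bin <- rep(NA_integer_, n_win)
  ok <- !is.na(wx)
  win_bin[ok] <- bin_xy(wx[ok], wy[ok], arena)$bin
  list(win_bin = win_bin, n_win = n_win, duration_s = n_win * dt)
}

#' @export
print.ratemap_bundle <- function(x, ...) {
  cat(sprintf("<ratemap_bundle> %d x %d bins, %d events, %.0f%% bins visited%s\n",
              nrow(x$spike_counts), ncol(x$spike_counts), x$n_events_used,
              100 * x$prop_visited,
              if (!is.null(x$smoothed_rate)) ", smoothed" else ""))
  invisible(x)
}

#' Smooth a rate map with an isotropic Gaussian kernel
#'
#' Both the event-count histogram and the occupancy histogram are convolved
#' with the same Gaussian kernel (sd `sigma` bins, truncated at 3 sigma) and
#' the smoothed rate is their ratio, so edge bins are implicitly renormalised.
#' Bins whose smoothed occupancy is (numerically) zero stay undefined.
#'
#' @param bundle A [bin_session()] result.
#' @param sigma Kernel standard deviation in bins (default 1).
#' @return The bundle with `smoothed_spikes`, `smoothed_occupancy_s` and
#'   `smoothed_rate` added.
#' @export
smooth_rate_map <- function(bundle, sigma = 1) {
  if (all(bundle$occupancy_s == 0)) stop("all-zero occupancy", call. = FALSE)
  k <- gaussian_kernel_2d(sigma)
  ss <- conv2_zero(bundle$spike_counts, k)
  so <- conv2_zero(bundle$occupancy_s, k)
  sr <- matrix(NA_real_, nrow(ss), ncol(ss))
  pos <- so > 1e-12
  sr[pos] <- ss[pos] / so[pos]
  bundle$smoothed_spikes <- ss
  bundle$smoothed_occupancy_s <- so
  bundle$smoothed_rate <- sr
  bundle$sigma <- sigma
  bundle
}

gaussian_kernel_2d <- function(sigma) {
  if (sigma <= 0) return(matrix(1, 1, 1))
  half <- max(1L, ceiling(3 * sigma))
  g <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

# 2-D convolution with zero padding (mass-preserving for interior sources)
conv2_zero <- function(m, k) {
  hn <- (nrow(k) - 1L) %/% 2L
  hm <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (di in -hn:hn) {
    for (dj in -hm:hm) {
      w <- k[di + hn + 1L, dj + hm + 1L]
      if (w == 0) next
      si <- max(1L, 1L - di):min(nr, nr - di)
      sj <- max(1L, 1L - dj):min(nc, nc - dj)
      out[si + di, sj + dj] <- out[si + di, sj + dj] + w * m[si, sj]
    }
  }
  out
}

#' Skaggs spatial information
#'
#' Information per event conveyed about position:
#' `I = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' `p_i` the occupancy share of bin i, `lambda_i` its event rate and
#' `lambda_bar` the occupancy-weighted mean rate. Bins with zero rate
#' contribute zero. Computed on the raw (unsmoothed) map by default, which
#' makes the closed-form identities exact (a cell firing only in 1 of k
#' equally occupied bins carries exactly `log2(k)` bits/event).
#'
#' @param bundle A [bin_session()] result.
#' @param use_smoothed Use the Gaussian-smoothed maps instead (requires
#'   [smooth_rate_map()]).
#' @return Information in bits/event.
#' @export
skaggs_information <- function(bundle, use_smoothed = FALSE) {
  if (use_smoothed) {
    if (is.null(bundle$smoothed_rate)) stop("bundle has no smoothed maps",
                                            call. = FALSE)
    occ <- bundle$smoothed_occupancy_s
    counts <- bundle$smoothed_spikes
  } else {
    occ <- bundle$occupancy_s
    counts <- bundle$spike_counts
  }
  info_from_counts(as.numeric(counts), as.numeric(occ))
}

# shared kernel: information from per-bin counts and occupancy seconds
info_from_counts <- function(counts, occ_s) {
  tot_occ <- sum(occ_s)
  tot_ev <- sum(counts)
  if (tot_occ <= 0) stop("zero total occupancy", call. = FALSE)
  if (tot_ev <= 0) stop("no events: information undefined", call. = FALSE)
  vis <- occ_s > 0
  p <- occ_s[vis] / tot_occ
  lam <- counts[vis] / occ_s[vis]
  lbar <- tot_ev / tot_occ
  rel <- lam / lbar
  pos <- rel > 0
  sum(p[pos] * rel[pos] * log2(rel[pos]))
}
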