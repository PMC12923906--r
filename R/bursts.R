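#' Z-scored population activity signal
#'
#' Each cell's ΔF/F trace is z-scored, the z-scored traces are averaged
#' across cells per frame, and the resulting population mean is z-scored
#' again, yielding a signal with mean 0 and unit standard deviation.
#' Zero-variance traces carry no activity information and are dropped with a
#' warning before averaging.
#'
#' @param traces Numeric matrix, cells x frames.
#' @return Numeric vector of length `ncol(traces)`.
#' @export
population_zscore <- function(traces) {
  if (!is.matrix(traces) || nrow(traces) < 1) {
    stop("traces must be a non-empty cells x frames matrix", call. = FALSE)
  }
  sds <- apply(traces, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance trace(s) excluded from the population signal",
            call. = FALSE)
    traces <- traces[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (nrow(traces) == 0) stop("no cells with nonzero variance", call. = FALSE)
  }
  z <- (traces - rowMeans(traces)) / sds
  pop <- colMeans(z)
  (pop - mean(pop)) / stats::sd(pop)
}

#' Detect population bursts
#'
#' Candidate bursts are maximal runs of frames where the population z-score
#' strictly exceeds `z_threshold`; runs shorter than `min_duration_s` are
#' discarded as transient fluctuations. A burst's onset is the time of the
#' first supra-threshold frame, its duration is the run length in frames
#' divided by the frame rate, its magnitude the mean z over the run, and its
#' peak the frame of maximal z.
#'
#' @param popz Population z-score signal (see [population_zscore()]).
#' @param fps Frame rate (frames/s).
#' @param z_threshold Threshold in z-units (default 2).
#' @param min_duration_s Minimum burst duration in seconds (default 0.05).
#' @return A tibble with one row per burst: `onset_s`, `offset_s`,
#'   `duration_s`, `peak_time_s`, `peak_z`, `magnitude` (mean z),
#'   `n_frames`.
#' @export
detect_bursts <- function(popz, fps, z_threshold = 2, min_duration_s = 0.05) {
  if (any(!is.finite(popz))) stop("population signal must be finite",
                                  call. = FALSE)
  above <- popz > z_threshold
  if (!any(above)) return(empty_bursts())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  dur <- (ends - starts + 1) / fps
  ok <- dur >= min_duration_s
  if (!any(ok)) return(empty_bursts())
  starts <- starts[ok]; ends <- ends[ok]; dur <- dur[ok]
  peak_idx <- mapply(function(a, b) a - 1 + which.max(popz[a:b]), starts, ends)
  tibble::tibble(
    onset_s = (starts - 1) / fps,
    offset_s = (starts - 1) / fps + dur,
    duration_s = dur,
    peak_time_s = (peak_idx - 1) / fps,
    peak_z = popz[peak_idx],
    magnitude = mapply(function(a, b) mean(popz[a:b]), starts, ends),
    n_frames = as.integer(ends - starts + 1))
}

empty_bursts <- function() {
  tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                 duration_s = numeric(), peak_time_s = numeric(),
                 peak_z = numeric(), magnitude = numeric(),
                 n_frames = integer())
}

#' Session-level burst aggregates
#'
#' @param bursts A burst tibble from [detect_bursts()].
#' @return One-row tibble: `n_bursts`, `mean_duration_s`, `mean_magnitude`,
#'   `mean_peak_z` (means are `NA` when no bursts were detected).
#' @export
burst_session_metrics <- function(bursts) {
  if (nrow(bursts) == 0) {
    return(tibble::tibble(n_bursts = 0L, mean_duration_s = NA_real_,
                          mean_magnitude = NA_real_, mean_peak_z = NA_real_))
  }
  tibble::tibble(n_bursts = nrow(bursts),
                 mean_duration_s = mean(bursts$duration_s),
                 mean_magnitude = mean(bursts$magnitude),
                 mean_peak_z = mean(bursts$peak_z))
}

#' Per-burst neuronal participation
#'
#' A neuron participates in a burst if it has at least one deconvolved event
#' in `[onset_s, offset_s]`; the participation fraction is participants over
#' all neurons considered.
#'
#' @param events Named list of per-cell event-time vectors (see
#'   [event_trains()]) or an event tibble with `cell_id`, `time_s` plus
#'   `n_cells`.
#' @param bursts A burst tibble.
#' @param n_cells Total neuron count (required when `events` is a tibble and
#'   silent cells would otherwise be invisible).
#' @return The burst tibble with a `participation_frac` column added.
#' @export
burst_participation <- function(events, bursts, n_cells = NULL) {
  if (is.data.frame(events)) {
    stopifnot(!is.null(n_cells))
    trains <- split(events$time_s, events$cell_id)
    n <- n_cells
  } else {
    trains <- events
    n <- length(trains)
  }
  frac <- vapply(seq_len(nrow(bursts)), function(i) {
    sum(vapply(trains, function(tt)
      any(tt >= bursts$onset_s[i] & tt <= bursts$offset_s[i]), TRUE)) / n
  }, 0)
  bursts$participation_frac <- if (nrow(bursts)) frac else numeric(0)
  bursts
}

#' Correlation between population activity and running speed
#'
#' Spearman rank correlation between the population z-score and the animal's
#' speed sampled on the imaging frame clock (speed is linearly interpolated
#' to frame times). Optionally restricted to burst frames.
#'
#' @param popz Population z-score signal.
#' @param trajectory Trajectory tibble with `t` and `speed`.
#' @param fps Frame rate.
#' @param bursts Optional burst tibble; when given, the correlation is also
#'   computed over frames inside bursts only.
#' @return A tibble with `scope` (`"session"` / `"burst_frames"`), `rho` and
#'   `n_frames`.
#' @export
activity_speed_correlation <- function(popz, trajectory, fps, bursts = NULL) {
  if (is.null(trajectory[["speed"]])) trajectory <- compute_speed(trajectory)
  tf <- (seq_along(popz) - 1) / fps
  sp <- stats::approx(trajectory$t, trajectory$speed, xout = tf, rule = 2)$y
  if (stats::sd(popz) == 0 || stats::sd(sp) == 0) {
    stop("constant signal: speed correlation undefined", call. = FALSE)
  }
  out <- tibble::tibble(scope = "session",
                        rho = stats::cor(popz, sp, method = "spearman"),
                        n_frames = length(popz))
  if (!is.null(bursts) && nrow(bursts) > 0) {
    inb <- rep(FALSE, length(popz))
    for (i in seq_len(nrow(bursts))) {
      inb[tf >= bursts$onset_s[i] & tf <= bursts$offset_s[i]] <- TRUE
    }
    if (sum(inb) >= 3 && stats::sd(popz[inb]) > 0 && stats::sd(sp[inb]) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        scope = "burst_frames",
        rho = stats::cor(popz[inb], sp[inb], method = "spearman"),
        n_frames = sum(inb)))
    }
  }
  out
}

#' Burst-triggered speed profile
#'
#' Average running speed aligned to burst peaks over a symmetric window,
#' with a peak-versus-flank contrast: the speed at the peak-centred bin minus
#' the mean of the two window-edge bins. Bursts whose window extends past the
#' session edges are skipped.
#'
#' @param trajectory Trajectory tibble with `t` and `speed`.
#' @param bursts Burst tibble with `peak_time_s`.
#' @param window_s Half-window (s); the study design looks at 2.5 and 5 s.
#' @param bin_s Profile resolution (s; default 0.25).
#' @return A list with `profile` (tibble `offset_s`, `mean_speed`, `n`),
#'   `contrast` (peak minus flank mean, cm/s) and `n_bursts` used.
#' @export
burst_triggered_speed <- function(trajectory, bursts, window_s = 5,
                                  bin_s = 0.25) {
  if (is.null(trajectory[["speed"]])) trajectory <- compute_speed(trajectory)
  t0 <- min(trajectory$t); t1 <- max(trajectory$t)
  peaks <- bursts$peak_time_s
  peaks <- peaks[peaks - window_s >= t0 & peaks + window_s <= t1]
  if (length(peaks) == 0) stop("no bursts with a full window inside the session",
                               call. = FALSE)
  offsets <- seq(-window_s, window_s, by = bin_s)
  mat <- vapply(peaks, function(p)
    stats::approx(trajectory$t, trajectory$speed, xout = p + offsets,
                  rule = 2)$y, numeric(length(offsets)))
  mat <- matrix(mat, nrow = length(offsets))
  profile <- tibble::tibble(offset_s = offsets, mean_speed = rowMeans(mat),
                            n = length(peaks))
  peak_bin <- which.min(abs(offsets))
  flank <- c(1L, length(offsets))
  list(profile = profile,
       contrast = profile$mean_speed[peak_bin] - mean(profile$mean_speed[flank]),
       n_bursts = length(peaks))
}
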