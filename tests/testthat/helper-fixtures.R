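# Shared fixtures and independent brute-force oracles. Every oracle here is a
# direct, naive recomputation kept deliberately separate from the package's
# code paths.

test_arena <- function(objects = NULL) arena_config(objects = objects)

# trajectory sampled every `dt_s` with one sample per spatial down-sampling
# window, cycling through the given bin centres
cycling_trajectory <- function(arena, bin_ids, n_windows, dt_s = 0.5) {
  ctr <- bin_centers(arena)
  seqi <- rep_len(bin_ids, n_windows)
  tibble::tibble(t = (seq_len(n_windows) - 1) * dt_s,
                 x = ctr$x[match(seqi, ctr$bin_x + (ctr$bin_y - 1) * arena$n_bins_x)],
                 y = ctr$y[match(seqi, ctr$bin_x + (ctr$bin_y - 1) * arena$n_bins_x)])
}

small_session <- function(seed = 1, n_cells = 5, duration_s = 60, fps = 20) {
  meta <- recording_meta("S1", fps = fps, duration_s = duration_s,
                         animal_id = "t1", group_label = "vehicle")
  arena <- arena_config(objects = data.frame(object_id = c("a", "b"),
                                             x = c(12, 28), y = c(20, 20)))
  traj <- simulate_trajectory(arena, meta, seed = seed)
  cells <- tibble::tibble(
    global_id = sprintf("c%02d", seq_len(n_cells)),
    base_rate_hz = 0.5, place_cell = FALSE,
    center_x = 20, center_y = 20, width_cm = 5, peak_gain = 1)
  simulate_session(cells, traj, meta, arena, seed = seed + 1)
}

# --- oracles ---------------------------------------------------------------

oracle_speed <- function(traj) {
  n <- nrow(traj)
  sp <- numeric(n)
  for (i in 2:n) {
    sp[i] <- sqrt((traj$x[i] - traj$x[i - 1])^2 +
                    (traj$y[i] - traj$y[i - 1])^2) /
      (traj$t[i] - traj$t[i - 1])
  }
  sp[1] <- sp[2]
  sp
}

# per-window loop assignment of occupancy and events
oracle_bin <- function(traj, events, arena, dt = 0.5) {
  n_win <- ceiling((max(traj$t) + 1e-9) / dt)
  occ <- matrix(0, arena$n_bins_x, arena$n_bins_y)
  cnt <- matrix(0, arena$n_bins_x, arena$n_bins_y)
  wbin <- rep(NA_integer_, n_win)
  for (w in seq_len(n_win)) {
    inw <- traj$t >= (w - 1) * dt & traj$t < w * dt
    if (w == n_win) inw <- inw | traj$t >= w * dt
    if (!any(inw)) next
    b <- bin_xy(mean(traj$x[inw]), mean(traj$y[inw]), arena)
    occ[b$bin_x, b$bin_y] <- occ[b$bin_x, b$bin_y] + dt
    wbin[w] <- b$bin
  }
  for (e in events) {
    w <- min(floor(e / dt) + 1, n_win)
    b <- wbin[w]
    if (!is.na(b)) cnt[b] <- cnt[b] + 1
  }
  list(occupancy = occ, counts = cnt)
}

# term-by-term Skaggs information from count/occupancy grids
oracle_skaggs <- function(counts, occ) {
  p <- occ / sum(occ)
  lbar <- sum(counts) / sum(occ)
  tot <- 0
  for (i in seq_along(counts)) {
    if (occ[i] > 0 && counts[i] > 0) {
      lam <- counts[i] / occ[i]
      tot <- tot + p[i] * (lam / lbar) * log2(lam / lbar)
    }
  }
  tot
}

# threshold-run enumeration of bursts
oracle_bursts <- function(z, fps, thr = 2, min_dur = 0.05) {
  runs <- list()
  i <- 1
  n <- length(z)
  while (i <= n) {
    if (z[i] > thr) {
      j <- i
      while (j < n && z[j + 1] > thr) j <- j + 1
      if ((j - i + 1) / fps >= min_dur) {
        runs[[length(runs) + 1]] <- c(start = i, end = j)
      }
      i <- j + 1
    } else i <- i + 1
  }
  runs
}

# brute-force weighted centralities on a symmetric weight matrix (0 = no edge)
oracle_degree <- function(W) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) sum(W[i, ] > 0)) / (n - 1)
}

oracle_barrat <- function(W) {
  n <- nrow(W)
  A <- (W > 0) * 1
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k < 2) next
    s <- sum(W[i, ])
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        acc <- acc + (W[i, j] + W[i, h]) / 2 * A[i, j] * A[i, h] * A[j, h]
      }
    }
    out[i] <- acc / (s * (k - 1))
  }
  out
}

oracle_closeness <- function(W, distance = c("inverse", "one_minus")) {
  distance <- match.arg(distance)
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) {
      D[i, j] <- if (distance == "inverse") 1 / W[i, j] else 1 - W[i, j]
    }
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  sapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0 || mean(d) == 0) 0 else 1 / mean(d)
  })
}

random_weight_matrix <- function(n, p_edge = 0.6) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      W[i, j] <- W[j, i] <- stats::runif(1, 0.05, 1)
    }
  }
  W
}

graph_from_weights <- function(W) {
  rownames(W) <- colnames(W) <- paste0("v", seq_len(nrow(W)))
  igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
}
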