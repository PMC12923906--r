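test_that("session binning conserves occupancy and matches the loop oracle", {
  ar <- test_arena()
  meta <- recording_meta("S1", duration_s = 120)
  traj <- simulate_trajectory(ar, meta, seed = 14)
  set.seed(14)
  events <- sort(runif(80, 0, 120))
  bundle <- bin_session(traj, events, ar, dt = 0.5)
  # conservation: occupancy sums to the session duration, counts to events
  expect_lt(abs(sum(bundle$occupancy_s) - 120), 0.5 + 1e-9)
  expect_equal(sum(bundle$spike_counts), length(events))
  ob <- oracle_bin(traj, events, ar, dt = 0.5)
  expect_equal(bundle$occupancy_s, ob$occupancy)
  expect_equal(bundle$spike_counts, ob$counts)
  # confinement to one bin
  still <- tibble::tibble(t = seq(0, 60, by = 0.05), x = 2, y = 2)
  b2 <- bin_session(still, numeric(0), ar)
  expect_equal(b2$prop_visited, 1 / 100)
  expect_equal(sum(b2$occupancy_s > 0), 1)
  expect_error(bin_session(traj, 500, ar), "outside")
})

test_that("Gaussian smoothing preserves constants and spike mass", {
  ar <- test_arena()
  # uniform occupancy + uniform spikes: rate unchanged by smoothing
  bundle <- structure(list(
    spike_counts = matrix(2, 10, 10), occupancy_s = matrix(1, 10, 10),
    visited = matrix(TRUE, 10, 10),
    raw_rate = matrix(2, 10, 10), arena = ar, dt = 0.5,
    n_events_used = 200L, prop_visited = 1), class = "ratemap_bundle")
  sm <- smooth_rate_map(bundle, sigma = 1)
  inner <- sm$smoothed_rate[4:7, 4:7]
  expect_true(all(abs(inner - 2) < 1e-9))
  # edge bins keep the constant rate because spike and occupancy histograms
  # lose mass identically
  expect_true(all(abs(sm$smoothed_rate - 2) < 1e-9))
  # single spike at the grid centre: smoothed spike mass sums to 1
  one <- bundle
  one$spike_counts <- matrix(0, 10, 10)
  one$spike_counts[5, 5] <- 1
  sm1 <- smooth_rate_map(one, sigma = 1)
  expect_equal(sum(sm1$smoothed_spikes), 1, tolerance = 1e-12)
  # sigma -> 0 limit: identity kernel
  sm0 <- smooth_rate_map(one, sigma = 0)
  expect_equal(sm0$smoothed_spikes, one$spike_counts)
  expect_error(smooth_rate_map(structure(list(occupancy_s = matrix(0, 2, 2)),
                                         class = "ratemap_bundle")),
               "all-zero")
})

test_that("Skaggs information has its closed forms and matches the term oracle", {
  ar <- test_arena()
  # trajectory visiting k bins equally, firing only in the first -> log2(k)
  for (k in c(2, 4, 16)) {
    traj <- cycling_trajectory(ar, seq_len(k), n_windows = 40 * k)
    fire_win <- which(rep_len(seq_len(k), 40 * k) == 1)
    events <- (fire_win - 1) * 0.5 + 0.25
    bundle <- bin_session(traj, events, ar)
    expect_equal(skaggs_information(bundle), log2(k), tolerance = 1e-12)
  }
  # uniform firing over uniformly occupied bins -> 0 bits
  traj <- cycling_trajectory(ar, 1:4, n_windows = 160)
  events_all <- (seq_len(160) - 1) * 0.5 + 0.25
  expect_equal(skaggs_information(bin_session(traj, events_all, ar)), 0,
               tolerance = 1e-12)
  # random fixture vs term-by-term oracle
  meta <- recording_meta("S1", duration_s = 120)
  rtraj <- simulate_trajectory(ar, meta, seed = 31)
  set.seed(31)
  rev_t <- sort(runif(60, 0, 120))
  rb <- bin_session(rtraj, rev_t, ar)
  expect_equal(skaggs_information(rb),
               oracle_skaggs(rb$spike_counts, rb$occupancy_s))
  expect_gte(skaggs_information(rb), 0)
  empty <- bin_session(rtraj, numeric(0), ar)
  expect_error(skaggs_information(empty), "no events")
})

test_that("circular-shuffle p-values behave at the boundaries and detect planted tuning", {
  ar <- test_arena()
  meta <- recording_meta("S1", duration_s = 600)
  traj <- simulate_trajectory(ar, meta, seed = 40)
  # strongly tuned planted cell: p = 0
  cells <- tibble::tibble(global_id = "pc", base_rate_hz = 0.4,
                          place_cell = TRUE, center_x = 10, center_y = 30,
                          width_cm = 4, peak_gain = 10)
  ss <- simulate_session(cells, traj, meta, ar, seed = 41)
  expect_gte(length(ss$events$time_s), 100)
  res <- shuffle_p_value(traj, ss$events$time_s, ar, n_shuffles = 500,
                         seed = 42)
  expect_equal(res$p_value, 0)
  # n = 1 with shuffled score below observed -> p = 0 by the counting rule
  res1 <- shuffle_p_value(traj, ss$events$time_s, ar, n_shuffles = 1,
                          seed = 43)
  expect_true(res1$p_value %in% c(0, 1))
  expect_equal(res1$p_value,
               mean(res1$info_shuffled >= res1$info_observed))
  # reproducibility
  resa <- shuffle_p_value(traj, ss$events$time_s, ar, n_shuffles = 50, seed = 7)
  resb <- shuffle_p_value(traj, ss$events$time_s, ar, n_shuffles = 50, seed = 7)
  expect_identical(resa, resb)
  expect_error(shuffle_p_value(traj[traj$t < 15, ],
                               c(1, 2, 3), ar, min_shift_s = 10),
               "too short")
})

test_that("classification needs both significance and adequate sampling", {
  expect_true(classify_place_cell(0.01, 50))
  expect_false(classify_place_cell(0.01, 19))
  expect_false(classify_place_cell(0.05, 50))  # strict inequality
  expect_false(classify_place_cell(0.2, 50))
  expect_equal(classify_place_cell(c(0.01, 0.04), c(25, 10)), c(TRUE, FALSE))
})

test_that("field extraction thresholds at 20% of peak with 4-connectivity", {
  ar5 <- arena_config(width_cm = 20, height_cm = 20, n_bins_x = 5, n_bins_y = 5)
  # plus-shaped field: peak 10 centred, ring of 3 on the plus, background 1
  rate <- matrix(1, 5, 5)
  rate[3, 3] <- 10
  rate[2, 3] <- rate[4, 3] <- rate[3, 2] <- rate[3, 4] <- 3
  f <- extract_fields(rate, ar5, threshold_frac = 0.2)
  expect_equal(nrow(f), 1)
  expect_equal(f$n_bins, 5)
  expect_equal(f$size_cm2, 80)
  expect_equal(f$centroid_x, 10)  # plus is centred on the arena centre
  expect_equal(f$centroid_y, 10)
  # single nonzero bin: one field of one bin (16 cm^2) centred on it
  single <- matrix(0, 5, 5)
  single[2, 4] <- 1
  f1 <- extract_fields(single, ar5)
  expect_equal(f1$size_cm2, 16)
  expect_equal(c(f1$centroid_x, f1$centroid_y), c(6, 14))
  # opposite corners: two disconnected fields
  two <- matrix(0, 5, 5)
  two[1, 1] <- 5; two[5, 5] <- 5
  expect_equal(nrow(extract_fields(two, ar5)), 2)
  # diagonal contact is NOT contiguous under 4-connectivity
  diagm <- matrix(0, 5, 5)
  diagm[2, 2] <- 5; diagm[3, 3] <- 5
  expect_equal(nrow(extract_fields(diagm, ar5)), 2)
  expect_error(extract_fields(matrix(0, 5, 5), ar5), "no positive peak")
})

test_that("extracted fields partition the supra-threshold set", {
  ar <- test_arena()
  set.seed(77)
  for (i in 1:50) {
    rate <- matrix(rexp(100), 10, 10)
    rate[sample(100, 20)] <- 0
    f <- extract_fields(rate, ar, threshold_frac = 0.2)
    supra <- which(rate >= 0.2 * max(rate))
    got <- unlist(lapply(f$bins, function(b) b$bin_x + (b$bin_y - 1) * 10))
    expect_setequal(got, supra)
    expect_equal(length(got), length(unique(got)))
    expect_equal(sum(f$size_cm2), length(supra) * 16)
  }
})

test_that("spatial coherence equals the neighbour-mean correlation oracle", {
  ar <- test_arena()
  meta <- recording_meta("S1", duration_s = 300)
  traj <- simulate_trajectory(ar, meta, seed = 55)
  set.seed(55)
  events <- sort(runif(300, 0, 300))
  bundle <- bin_session(traj, events, ar)
  z <- spatial_coherence(bundle)
  # double-loop oracle
  vis <- bundle$visited
  raw <- bundle$raw_rate
  av <- bv <- c()
  for (i in 1:10) for (j in 1:10) {
    if (!vis[i, j]) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 10 && jj >= 1 && jj <= 10 && vis[ii, jj]) {
        nb <- c(nb, raw[ii, jj])
      }
    }
    if (length(nb)) {
      av <- c(av, raw[i, j]); bv <- c(bv, mean(nb))
    }
  }
  expect_equal(z, atanh(cor(av, bv)), tolerance = 1e-12)
  # constant map is undefined
  const <- bundle
  const$raw_rate[const$visited] <- 1
  expect_error(spatial_coherence(const), "constant")
  # smoothing increases coherence on event-driven maps
  sm <- smooth_rate_map(bundle)
  sm_as_raw <- bundle
  sm_as_raw$raw_rate <- sm$smoothed_rate
  sm_as_raw$visited <- !is.na(sm$smoothed_rate)
  expect_gt(spatial_coherence(sm_as_raw), z)
})

test_that("object masks pad the centroid bin and clip at edges", {
  # object at the arena centre -> full 5x5 block
  ar_c <- arena_config(objects = data.frame(object_id = "c", x = 20, y = 20))
  expect_equal(sum(object_mask(ar_c, pad = 2)), 25)
  # corner object -> clipped to 3x3
  ar_k <- arena_config(objects = data.frame(object_id = "k", x = 1, y = 1))
  expect_equal(sum(object_mask(ar_k, pad = 2)), 9)
  expect_equal(sum(object_mask(arena_config(), pad = 2)), 0)
  # union over two objects
  ar_2 <- arena_config(objects = data.frame(object_id = c("a", "b"),
                                            x = c(20, 22), y = c(20, 20)))
  m2 <- object_mask(ar_2, pad = 2)
  expect_true(sum(m2) < 50 && sum(m2) >= 25)
})

test_that("object scores are overlap fractions of field bins", {
  ar5 <- arena_config(width_cm = 20, height_cm = 20, n_bins_x = 5, n_bins_y = 5)
  rate <- matrix(0, 5, 5)
  rate[2:3, 2:3] <- 5  # one 4-bin field
  f <- extract_fields(rate, ar5)
  mask_all <- matrix(TRUE, 5, 5)
  expect_equal(object_score(f, mask_all), 1)
  expect_equal(object_score(f, matrix(FALSE, 5, 5)), 0)
  half <- matrix(FALSE, 5, 5)
  half[2, 2:3] <- TRUE  # 2 of the 4 field bins
  expect_equal(object_score(f, half), 0.5)
  expect_equal(object_score(f, half, method = "per_field_mean"), 0.5)
  expect_error(object_score(f[0, ], mask_all), "no fields")
})

test_that("the per-session spatial table flags planted place cells only", {
  ar <- test_arena()
  meta <- recording_meta("S1", duration_s = 300)
  traj <- simulate_trajectory(ar, meta, seed = 60)
  cells <- tibble::tibble(
    global_id = c("place1", "flat1", "sparse1"),
    base_rate_hz = c(0.4, 0.3, 0.02),
    place_cell = c(TRUE, FALSE, FALSE),
    center_x = 30, center_y = 30, width_cm = 4,
    peak_gain = c(10, 1, 1))
  ss <- simulate_session(cells, traj, meta, ar, seed = 61)
  cfg <- analysis_config(spatial = list(n_shuffles = 200, min_shift_s = 10),
                         seed = 5)
  tab <- analyze_spatial_cells(ss, cfg)
  expect_equal(nrow(tab), 3)
  expect_true(tab$is_place_cell_like[tab$cell_id == "place1"])
  expect_false(tab$is_place_cell_like[tab$cell_id == "sparse1"])
  # sparse cell below min_events never enters the shuffle test
  expect_true(is.na(tab$p_value[tab$cell_id == "sparse1"]))
  expect_true(all(tab$object_score >= 0 & tab$object_score <= 1, na.rm = TRUE))
})
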