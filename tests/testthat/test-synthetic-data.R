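test_that("simulated trajectories stay in bounds, are reproducible, and have the right length", {
  ar <- test_arena()
  meta <- recording_meta("HA", fps = 20, duration_s = 600)
  tr1 <- simulate_trajectory(ar, meta, seed = 11)
  expect_equal(nrow(tr1), 12000)
  expect_true(all(tr1$x >= 0 & tr1$x <= 40 & tr1$y >= 0 & tr1$y <= 40))
  tr2 <- simulate_trajectory(ar, meta, seed = 11)
  expect_identical(tr1, tr2)
  expect_false(identical(tr1$x, simulate_trajectory(ar, meta, seed = 12)$x))
  expect_error(simulate_trajectory(ar, meta, mobility = list(tau_s = -1)),
               "positive")
})

test_that("planted place tuning shows up where it was planted", {
  ar <- test_arena()
  meta <- recording_meta("S1", fps = 20, duration_s = 600)
  traj <- simulate_trajectory(ar, meta, seed = 2)
  cells <- tibble::tibble(global_id = "pc1", base_rate_hz = 0.3,
                          place_cell = TRUE, center_x = 30, center_y = 10,
                          width_cm = 4, peak_gain = 8)
  ss <- simulate_session(cells, traj, meta, ar, seed = 5)
  # brute-force rate map of the generated events: the peak-rate bin must lie
  # within one bin of the planted tuning centre
  ob <- oracle_bin(traj, ss$events$time_s, ar, dt = 0.5)
  rate <- ifelse(ob$occupancy > 0, ob$counts / ob$occupancy, 0)
  pk <- which(rate == max(rate), arr.ind = TRUE)[1, ]
  ctr_bin <- bin_xy(30, 10, ar)
  expect_lte(abs(pk[1] - ctr_bin$bin_x), 1)
  expect_lte(abs(pk[2] - ctr_bin$bin_y), 1)
})

test_that("zero base rate yields zero events and noise-only traces", {
  ar <- test_arena()
  meta <- recording_meta("S1", fps = 20, duration_s = 60)
  traj <- simulate_trajectory(ar, meta, seed = 3)
  cells <- tibble::tibble(global_id = c("a", "b"), base_rate_hz = 0,
                          place_cell = FALSE, center_x = 20, center_y = 20,
                          width_cm = 5, peak_gain = 1)
  ss <- simulate_session(cells, traj, meta, ar, seed = 4)
  expect_equal(nrow(ss$events), 0)
  # traces are pure Gaussian noise at the preset noise level
  expect_lt(abs(sd(ss$traces) - sim_preset()$noise_sd), 0.02)
  expect_error(simulate_session(dplyr::mutate(cells, place_cell = TRUE,
                                              center_x = 99),
                                traj, meta, ar), "inside the arena")
})

test_that("a planted burst inflates the windowed population event count", {
  ar <- test_arena()
  meta <- recording_meta("S2", fps = 20, duration_s = 600)
  traj <- simulate_trajectory(ar, meta, seed = 6)
  cells <- tibble::tibble(global_id = sprintf("c%02d", 1:50),
                          base_rate_hz = 0.2, place_cell = FALSE,
                          center_x = 20, center_y = 20, width_cm = 5,
                          peak_gain = 1)
  bursts <- tibble::tibble(time_s = 300, duration_s = 0.5,
                           participation_frac = 0.8, gain = 10)
  ss <- simulate_session(cells, traj, meta, ar, bursts = bursts, seed = 7)
  # windowed counting oracle: events in [299.5, 300.5 + dur] vs the session
  # median 1.5 s window count
  win_count <- function(t0) sum(ss$events$time_s >= t0 &
                                  ss$events$time_s < t0 + 1.5)
  burst_n <- win_count(299.5)
  null_n <- sapply(seq(0, 598, by = 1.5), win_count)
  expect_gt(burst_n, stats::median(null_n))
  expect_gt(burst_n, 2 * stats::median(null_n))
})

test_that("correlated blocks raise within-block trace correlations", {
  ar <- test_arena()
  meta <- recording_meta("S1", fps = 20, duration_s = 300)
  traj <- simulate_trajectory(ar, meta, seed = 8)
  cells <- tibble::tibble(global_id = sprintf("c%02d", 1:20),
                          base_rate_hz = 0.5, place_cell = FALSE,
                          center_x = 20, center_y = 20, width_cm = 5,
                          peak_gain = 1,
                          block_id = rep(c(1L, NA), each = 10))
  ss <- simulate_session(cells, traj, meta, ar, seed = 9)
  C <- stats::cor(t(ss$traces), method = "spearman")
  inblk <- C[1:10, 1:10][upper.tri(matrix(0, 10, 10))]
  between <- C[1:10, 11:20]
  expect_gt(mean(inblk), mean(between))
})

test_that("study-level overlap, registration and determinism behave as planned", {
  st <- simulate_study("vehicle_like", n_cells = 200, seed = 21,
                       duration_s = 60)
  # forced overlap extremes
  p1 <- sim_preset("vehicle_like", overlap = c("HA->S1" = 1, "S1->S2" = 1,
                                               "S2->S3" = 1), recruit_p = 0)
  st1 <- simulate_study(p1, n_cells = 50, seed = 1, duration_s = 60)
  expect_equal(reactivation_percent(st1$regmap, "S1", "S2"), 100)
  # moderate overlap recovered within binomial tolerance
  expect_lt(abs(reactivation_percent(st$regmap, "S1", "S2") - 80), 8)
  # registration indices are unique per session
  for (s in session_labels()) {
    idx <- st$regmap[[s]]
    expect_false(any(duplicated(idx[!is.na(idx)])))
  }
  expect_error(sim_preset("vehicle_like", overlap = c("HA->S1" = 1.2,
                                                      "S1->S2" = 1,
                                                      "S2->S3" = 1)),
               "\\[0, 1\\]")
  expect_error(simulate_study(n_cells = 10), ">= 20")
})

test_that("identical seeds give byte-identical study trees", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study("antagonist_like", n_cells = 25, seed = 5,
                             duration_s = 30), d1)
  write_study(simulate_study("antagonist_like", n_cells = 25, seed = 5,
                             duration_s = 30), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})
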