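test_that("population z-score is the two-step normalisation", {
  set.seed(1)
  # single cell: z of z is the z-score itself
  tr <- matrix(rnorm(200, 5, 2), 1)
  rownames(tr) <- "a"
  z1 <- population_zscore(tr)
  expect_equal(z1, as.numeric(scale(tr[1, ])), tolerance = 1e-12)
  # normalisation invariant
  tr3 <- matrix(rnorm(300), 3, 100, dimnames = list(letters[1:3], NULL))
  z3 <- population_zscore(tr3)
  expect_equal(mean(z3), 0, tolerance = 1e-9)
  expect_equal(sd(z3), 1, tolerance = 1e-9)
  # direct two-step hand computation on a 3 x 100 fixture
  zc <- t(apply(tr3, 1, function(r) (r - mean(r)) / sd(r)))
  pop <- colMeans(zc)
  expect_equal(z3, (pop - mean(pop)) / sd(pop), tolerance = 1e-12)
  # zero-variance cells are excluded with a warning
  tr4 <- rbind(tr3, flat = rep(7, 100))
  expect_warning(z4 <- population_zscore(tr4), "zero-variance")
  expect_equal(z4, z3)
  expect_error(population_zscore(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("burst detection enumerates maximal supra-threshold runs", {
  fps <- 20
  z <- rep(0, 200)
  expect_equal(nrow(detect_bursts(z, fps)), 0)
  # square pulse z=3 for 1.0 s -> one burst, duration 1.0 s, magnitude 3.0
  z[101:120] <- 3
  b <- detect_bursts(z, fps)
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_s, 1.0)
  expect_equal(b$magnitude, 3.0)
  expect_equal(b$onset_s, 100 / fps)
  expect_equal(b$offset_s, 120 / fps)
  # a 0.04 s pulse (4 frames at 100 fps) is below the minimum duration
  z2 <- rep(0, 1000)
  z2[500:503] <- 5
  expect_equal(nrow(detect_bursts(z2, fps = 100)), 0)
  # runs are maximal and never merged across a sub-threshold frame
  z3 <- rep(0, 100)
  z3[10:14] <- 3; z3[16:20] <- 3
  b3 <- detect_bursts(z3, fps)
  expect_equal(nrow(b3), 2)
  expect_true(all(b3$offset_s[-nrow(b3)] <= b3$onset_s[-1]))
  # strict inequality at the threshold
  z4 <- rep(2, 100)
  expect_equal(nrow(detect_bursts(z4, fps)), 0)
})

test_that("burst detection matches the run-enumeration oracle on noisy signals", {
  set.seed(5)
  z <- as.numeric(arima.sim(list(ar = 0.9), 3000, sd = 1))
  z <- (z - mean(z)) / sd(z)
  b <- detect_bursts(z, fps = 20)
  runs <- oracle_bursts(z, fps = 20)
  expect_equal(nrow(b), length(runs))
  for (k in seq_along(runs)) {
    expect_equal(b$onset_s[k], (runs[[k]]["start"] - 1) / 20,
                 ignore_attr = TRUE)
    expect_equal(b$n_frames[k], unname(runs[[k]]["end"] - runs[[k]]["start"] + 1L))
    expect_equal(b$magnitude[k],
                 mean(z[runs[[k]]["start"]:runs[[k]]["end"]]))
  }
})

test_that("burst detection is invariant to positive affine rescaling of the traces", {
  set.seed(6)
  tr <- matrix(rnorm(20 * 500), 20, 500,
               dimnames = list(paste0("c", 1:20), NULL))
  tr[, 200:210] <- tr[, 200:210] + 4
  b1 <- detect_bursts(population_zscore(tr), fps = 20)
  b2 <- detect_bursts(population_zscore(tr * 3.7 + 11), fps = 20)
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("session metrics and participation aggregate correctly", {
  b <- tibble::tibble(onset_s = c(10, 20), offset_s = c(11, 22),
                      duration_s = c(1, 2), peak_time_s = c(10.5, 21),
                      peak_z = c(3, 4), magnitude = c(2.5, 3),
                      n_frames = c(20L, 40L))
  m <- burst_session_metrics(b)
  expect_equal(m$mean_duration_s, 1.5)
  expect_equal(m$mean_magnitude, 2.75)
  m0 <- burst_session_metrics(empty <- detect_bursts(rep(0, 10), 20))
  expect_equal(m0$n_bursts, 0L)
  expect_true(is.na(m0$mean_duration_s))
  # participation: every neuron with an event inside -> 1, none -> 0
  trains <- list(a = c(10.5, 50), b = 10.2, c = 21.5)
  bp <- burst_participation(trains, b)
  expect_equal(bp$participation_frac, c(2 / 3, 1 / 3))
  none <- tibble::tibble(onset_s = 90, offset_s = 91, duration_s = 1,
                         peak_time_s = 90.5, peak_z = 3, magnitude = 2.5,
                         n_frames = 20L)
  expect_equal(burst_participation(trains, none)$participation_frac, 0)
  all_in <- burst_participation(list(a = 10.1, b = 10.2, c = 10.9),
                                b[1, ])
  expect_equal(all_in$participation_frac, 1)
})

test_that("activity-speed correlation is a Spearman correlation on the frame clock", {
  meta <- recording_meta("S1", duration_s = 60)
  traj <- simulate_trajectory(test_arena(), meta, seed = 3)
  # activity proportional to speed -> rho = 1 (monotone invariance)
  popz <- as.numeric(scale(traj$speed * 3 + 1))
  out <- activity_speed_correlation(popz, traj, fps = 20)
  expect_equal(out$rho[out$scope == "session"], 1)
  # equals a direct rank correlation on a random fixture
  set.seed(8)
  popz2 <- rnorm(nrow(traj))
  out2 <- activity_speed_correlation(popz2, traj, fps = 20)
  expect_equal(out2$rho[1], cor(popz2, traj$speed, method = "spearman"))
  expect_error(activity_speed_correlation(rep(1, nrow(traj)), traj, 20),
               "constant")
})

test_that("burst-triggered speed profiles recover a planted locomotion bump", {
  meta <- recording_meta("S1", duration_s = 300)
  n <- 300 * 20
  tt <- (seq_len(n) - 1) / 20
  # constant speed -> flat profile, zero contrast
  traj_const <- tibble::tibble(t = tt, x = 20, y = 20, speed = 4)
  bursts <- tibble::tibble(peak_time_s = c(50, 150, 250))
  bt <- burst_triggered_speed(traj_const, bursts, window_s = 5)
  expect_equal(bt$contrast, 0)
  expect_true(all(abs(bt$profile$mean_speed - 4) < 1e-9))
  # planted speed bumps co-timed with bursts -> positive contrast
  speed <- rep(2, n)
  for (p in bursts$peak_time_s) speed <- speed + 6 * exp(-(tt - p)^2 / 2)
  traj_bump <- tibble::tibble(t = tt, x = 20, y = 20, speed = speed)
  bt2 <- burst_triggered_speed(traj_bump, bursts, window_s = 5)
  expect_gt(bt2$contrast, 1)
  # bursts too close to the session edge are excluded
  edge <- tibble::tibble(peak_time_s = c(1, 150))
  bt3 <- burst_triggered_speed(traj_bump, edge, window_s = 5)
  expect_equal(bt3$n_bursts, 1)
  expect_error(burst_triggered_speed(traj_bump,
                                     tibble::tibble(peak_time_s = 0.5),
                                     window_s = 5), "no bursts")
})
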