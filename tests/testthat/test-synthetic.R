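test_that("ping times follow the burst-interval random walk", {
  # zero noise: arithmetic sequence
  expect_equal(simulate_ping_times(4, 2.0, 0), c(0, 2, 4, 6))
  # fixed seed is bit-reproducible
  expect_identical(simulate_ping_times(50, 2, 1e-3, seed = 1),
                   simulate_ping_times(50, 2, 1e-3, seed = 1))
  # strictly increasing even with sizeable noise
  tt <- suppressWarnings(simulate_ping_times(200, 2, 0.05, seed = 2))
  expect_true(all(diff(tt) > 0))
  # second differences t(i) - 2 t(i-1) + t(i-2) have variance sigma_bi^2
  set.seed(3)
  sig <- 5e-3
  d2 <- unlist(lapply(1:2000, function(i) diff(diff(simulate_ping_times(7, 2, sig)))))
  expect_equal(sd(d2), sig, tolerance = 0.05)
})

test_that("track increments scale as 2 * D_xy * dt", {
  times <- seq(0, 8, by = 2)
  still <- simulate_track(times, 0, start = c(12, 34), seed = 1)
  expect_equal(still$x, rep(12, 5))
  expect_equal(still$y, rep(34, 5))
  tr <- simulate_track(seq(0, 2e4, by = 2), 1.0, seed = 4)
  expect_equal(var(diff(tr$x)), 4.0, tolerance = 0.1)  # 2 * 1 * 2
  expect_equal(var(diff(tr$y)), 4.0, tolerance = 0.1)
  expect_equal(cor(diff(tr$x), diff(tr$y)), 0, tolerance = 0.05)
})

test_that("sound-speed walk has variance 2 * D_v * dt and stays positive", {
  times <- seq(0, 8, by = 2)
  expect_equal(simulate_sound_speed(times, 1435, 0), rep(1435, 5))
  v <- simulate_sound_speed(seq(0, 2e4, by = 2), 1435, 0.01, seed = 5)
  expect_equal(var(diff(v)), 2 * 0.01 * 2, tolerance = 0.1)
  vv <- suppressWarnings(simulate_sound_speed(seq(0, 100, 2), 0.5, 0.05, seed = 6))
  expect_true(all(vv > 0))
})

test_that("clean TOA matrices reproduce the travel-time arithmetic exactly", {
  # transmitter (50,50), hydrophone (0,0), v = 1435: tau = sqrt(5000)/1435
  arr1 <- hydrophone_array(0, 0)
  track <- tibble::tibble(t = 0, x = 50, y = 50, v = 1435)
  toa <- build_toa(track, arr1, toa_noise_sd = 0)
  expect_equal(toa$h1, sqrt(50^2 + 50^2) / 1435, tolerance = 1e-12)
  # symmetry: centre of the quadrant is equidistant from all four corners
  corners <- hydrophone_array(c(0, 0, 100, 100), c(0, 100, 0, 100))
  tau <- as_toa_matrix(build_toa(track, corners, 0), corners)
  expect_true(diff(range(tau)) < 1e-12)
  # zero-noise matrices recompute from the truth to machine precision
  sim <- small_sim(toa_noise_sd = 0)
  mu <- predict_toa(sim$truth, sim$array)
  expect_equal(as_toa_matrix(sim$toa_clean, sim$array), mu, tolerance = 1e-12)
  # noisy residuals have sd toa_noise_sd
  sim2 <- simulate_tag(bench_array, sim_config(n_pings = 400, toa_noise_sd = 3e-4),
                       seed = 7)
  res <- as_toa_matrix(sim2$toa_clean, sim2$array) - predict_toa(sim2$truth, sim2$array)
  expect_equal(sd(res), 3e-4, tolerance = 0.05)
})

test_that("degradation applies Bernoulli missingness and bounded multipath", {
  sim <- small_sim(n_pings = 200)
  toa <- sim$toa_clean
  expect_identical(degrade_toa(toa, 0, 0, seed = 1), toa)
  # retention under p_na = 0.8 is ~20%, detect counts match the binomial mean
  deg <- degrade_toa(toa, 0.8, 0, seed = 2)
  kept <- mean(!is.na(as_toa_matrix(deg)))
  expect_equal(kept, 0.2, tolerance = 0.15)
  expect_equal(mean(detect_counts(deg)), 5 * 0.2, tolerance = 0.15)
  # multipath offsets are bounded by 100 m / 1435 m/s and hit ~p_mp of entries
  mp <- degrade_toa(toa, 0, 0.3, mp_max_m = 100, v = 1435, seed = 3)
  delta <- as_toa_matrix(mp) - as_toa_matrix(toa)
  expect_lte(max(abs(delta)), 100 / 1435)
  expect_equal(mean(delta != 0), 0.3, tolerance = 0.15)
  # seed-determinism of the degradation stream
  expect_identical(degrade_toa(toa, 0.5, 0.02, seed = 9),
                   degrade_toa(toa, 0.5, 0.02, seed = 9))
  expect_error(degrade_toa(toa, 1.2, 0), "p_na")
})

test_that("fraction of pings with >= 3 detections matches the binomial tail", {
  sim <- simulate_tag(bench_array, sim_config(n_pings = 500), seed = 8)
  p_na <- 0.4
  deg <- degrade_toa(sim$toa_clean, p_na, 0, seed = 10)
  frac3 <- mean(detect_counts(deg) >= 3)
  expected <- sum(dbinom(3:5, 5, 1 - p_na))
  expect_equal(frac3, expected, tolerance = 0.08)
})

test_that("hydrophone subsampling keeps rows and validates ids", {
  sim <- small_sim()
  all_ids <- sim$array$hydro
  same <- subsample_hydrophones(sim$toa, sim$array, all_ids)
  expect_equal(as_toa_matrix(same$toa, same$array),
               as_toa_matrix(sim$toa, sim$array))
  one <- subsample_hydrophones(sim$toa, sim$array, "h3")
  expect_equal(nrow(one$toa), nrow(sim$toa))  # rows kept even with 0 detections
  expect_true(all(detect_counts(one$toa) %in% 0:1))
  expect_error(subsample_hydrophones(sim$toa, sim$array, "h99"), "unknown")
  # with p_na = 0.5, keeping 3 of 5 columns leaves ~1.5 detections per ping
  deg <- degrade_toa(simulate_tag(bench_array, sim_config(n_pings = 400),
                                  seed = 11)$toa_clean, 0.5, 0, seed = 12)
  sub <- subsample_hydrophones(deg, bench_array, c("h1", "h3", "h5"))
  expect_equal(mean(detect_counts(sub$toa)), 1.5, tolerance = 0.1)
})

test_that("the full simulation is seed-reproducible", {
  s1 <- simulate_tag(bench_array, sim_config(n_pings = 40, p_na = 0.3, p_mp = 0.02),
                     seed = 13)
  s2 <- simulate_tag(bench_array, sim_config(n_pings = 40, p_na = 0.3, p_mp = 0.02),
                     seed = 13)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$toa, s2$toa)
  expect_true(all(s1$truth$v > 0))
  expect_true(!is.unsorted(s1$truth$t, strictly = TRUE))
})
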